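# Composite training loss: total = rpn_loss + roi_loss + pdn_cls_loss, with
# rpn_loss = rpn_loc_loss + rpn_cls_loss and roi_loss = roi_loc_loss +
# roi_cls_loss. Classification terms are cross-entropies on predicted
# probabilities (binary for RPN objectness, 3-way for the ROI head and the
# PDN); localization terms are smooth L1 on encoded deltas over positive
# samples only. The second-stage localization loss is smooth L1, not a
# cross-entropy: a cross-entropy on continuous offsets is ill-defined.

ce_clamp <- function(p) pmax(p, 1e-12)

#' Compute the five-term loss breakdown
#'
#' All score inputs are probabilities; perfect predictions (probability 1 on
#' the true class, exact boxes) give every term exactly 0. Localization
#' terms average the per-sample sum of elementwise smooth L1 over positive
#' samples and are 0 (with a log line) when there are none.
#'
#' @param predictions list with `rpn_objectness` (probabilities over sampled
#'   anchors), `rpn_deltas` (predicted encodings, positives only),
#'   `roi_scores` (`n x K`), `roi_deltas` (predicted encodings for the
#'   target class, positives only), `pdn_scores` (`n x K`).
#' @param targets list with `rpn_labels` (0/1), `rpn_delta_targets`,
#'   `roi_labels` (0-based class indices), `roi_delta_targets`,
#'   `pdn_labels` (0-based).
#' @return A one-row tibble of class `bc_loss_breakdown`: `rpn_cls_loss`,
#'   `rpn_loc_loss`, `roi_cls_loss`, `roi_loc_loss`, `pdn_cls_loss`, `total`.
#' @export
compute_losses <- function(predictions, targets) {
  p <- predictions; t <- targets
  rpn_cls <- if (length(t$rpn_labels))
    mean(-(t$rpn_labels * log(ce_clamp(p$rpn_objectness)) +
           (1 - t$rpn_labels) * log(ce_clamp(1 - p$rpn_objectness)))) else 0
  rpn_loc <- loc_term(p$rpn_deltas, t$rpn_delta_targets,
                      length(t$rpn_labels), "rpn")
  roi_cls <- if (length(t$roi_labels))
    mean(-log(ce_clamp(p$roi_scores[cbind(seq_along(t$roi_labels),
                                          t$roi_labels + 1L)]))) else 0
  roi_loc <- loc_term(p$roi_deltas, t$roi_delta_targets,
                      length(t$roi_labels), "roi")
  pdn_cls <- if (length(t$pdn_labels))
    mean(-log(ce_clamp(p$pdn_scores[cbind(seq_along(t$pdn_labels),
                                          t$pdn_labels + 1L)]))) else 0
  out <- tibble::tibble(rpn_cls_loss = rpn_cls, rpn_loc_loss = rpn_loc,
                        roi_cls_loss = roi_cls, roi_loc_loss = roi_loc,
                        pdn_cls_loss = pdn_cls)
  out$total <- rpn_cls + rpn_loc + roi_cls + roi_loc + pdn_cls
  class(out) <- c("bc_loss_breakdown", class(out))
  out
}

# localization term: elementwise smooth L1 over positive samples, summed
# and normalized by the total number of sampled candidates (positives and
# negatives), the normalization customary for two-stage detectors
loc_term <- function(pred, target, n_sampled, what) {
  if (is.null(pred) || !length(pred)) {
    bc_log(paste0(what, "_loc_positives"), 0)
    return(0)
  }
  pred <- matrix(pred, ncol = 4)
  target <- matrix(target, ncol = 4)
  sum(smooth_l1(pred - target)) / max(n_sampled, 1L)
}

# --- ground-truth assignment and sampling -----------------------------------

# Anchor labels: 1 = positive (IoU >= pos_iou with some ground-truth box, or
# the best anchor for a ground-truth box), 0 = negative (max IoU < neg_iou),
# NA = ignored. Returns per-anchor matched ground-truth index as well.
rpn_assign <- function(anchors, gt, config) {
  n <- nrow(box_matrix(anchors))
  if (is.null(gt) || nrow(gt) == 0)
    return(list(labels = rep(0, n), matched = rep(NA_integer_, n)))
  iou <- iou_matrix(anchors, gt)
  best <- apply(iou, 1, max)
  matched <- max.col(iou, ties.method = "first")
  labels <- rep(NA_real_, n)
  labels[best < config$rpn_neg_iou] <- 0
  labels[best >= config$rpn_pos_iou] <- 1
  # guarantee one positive per ground-truth box
  for (j in seq_len(ncol(iou))) {
    top <- which.max(iou[, j])
    labels[top] <- 1
    matched[top] <- j
  }
  list(labels = labels, matched = matched)
}

# Sample up to `batch` anchors with at most `batch/2` positives.
sample_balanced <- function(labels, batch) {
  pos <- which(!is.na(labels) & labels == 1)
  neg <- which(!is.na(labels) & labels == 0)
  if (length(pos) > batch %/% 2) pos <- sample(pos, batch %/% 2)
  n_neg <- min(length(neg), batch - length(pos))
  if (length(neg) > n_neg) neg <- sample(neg, n_neg)
  list(pos = pos, neg = neg)
}

# ROI labels against ground truth at the configured IoU threshold:
# 0 = background, otherwise the matched lesion class (1 benign, 2 malignant).
roi_assign <- function(rois, gt, gt_labels, config) {
  n <- nrow(box_matrix(rois))
  if (is.null(gt) || nrow(gt) == 0)
    return(list(labels = rep(0L, n), matched = rep(NA_integer_, n)))
  iou <- iou_matrix(rois, gt)
  best <- apply(iou, 1, max)
  matched <- max.col(iou, ties.method = "first")
  labels <- ifelse(best >= config$iou_threshold, gt_labels[matched], 0L)
  matched[labels == 0L] <- NA_integer_
  list(labels = as.integer(labels), matched = matched)
}
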