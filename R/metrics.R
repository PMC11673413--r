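# Evaluation metrics: confusion-count rates, VOC-style average precision at
# IoU 0.5 with the all-points precision envelope, ROC/AUC with the tie-aware
# trapezoidal rule (equal to the normalized Mann-Whitney U statistic), and
# the lesion-level tally used for sensitivity and false-positive rate.

#' Rates from confusion counts
#'
#' Sensitivity (= recall = TPR) `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)`, and false-positive rate `FP/(FP+TN)`. A rate
#' with a zero denominator is `NaN`, with a warning.
#'
#' @param counts a list/tibble with `TP`, `FP`, `TN`, `FN`.
#' @return A one-row tibble: `sensitivity`, `specificity`, `precision`,
#'   `fpr`.
#' @examples
#' confusion_rates(list(TP = 19, FN = 1, FP = 8, TN = 52))
#' @export
confusion_rates <- function(counts) {
  for (f in c("TP", "FP", "TN", "FN"))
    if (is.null(counts[[f]]) || counts[[f]] < 0)
      stop("counts must contain non-negative TP, FP, TN, FN")
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  with(counts, tibble::tibble(
    sensitivity = rate(TP, TP + FN, "sensitivity"),
    specificity = rate(TN, TN + FP, "specificity"),
    precision = rate(TP, TP + FP, "precision"),
    fpr = rate(FP, FP + TN, "fpr")))
}

# Greedy score-ordered matching of one class's detections to ground truth at
# an IoU threshold; returns cumulative precision/recall points at distinct
# score thresholds.
pr_points <- function(detections, ground_truth, iou_threshold = 0.5) {
  n_gt <- nrow(ground_truth)
  if (!nrow(detections))
    return(tibble::tibble(threshold = numeric(), recall = numeric(),
                          precision = numeric()))
  ord <- order(detections$score, decreasing = TRUE)
  det <- detections[ord, ]
  matched <- rep(FALSE, n_gt)
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(!matched & ground_truth$image_id == det$image_id[i])
    if (length(cand)) {
      ious <- iou_matrix(det[i, ], ground_truth[cand, ])[1, ]
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp[i] <- TRUE
        matched[cand[j]] <- TRUE
      }
    }
  }
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  # collapse to the last point of each distinct score
  last <- !duplicated(det$score, fromLast = TRUE)
  tibble::tibble(threshold = det$score[last],
                 recall = cum_tp[last] / n_gt,
                 precision = cum_tp[last] / (cum_tp[last] + cum_fp[last]))
}

envelope_ap <- function(pts) {
  if (!nrow(pts)) return(0)
  r <- c(0, pts$recall)
  p_env <- rev(cummax(rev(pts$precision)))
  sum((r[-1] - r[-length(r)]) * p_env)
}

#' Average precision at IoU 0.5
#'
#' Score-sorted detections are greedily matched to unmatched ground-truth
#' boxes of the same image at IoU >= `iou_threshold`; AP is the area under
#' the all-points precision envelope of the resulting precision-recall
#' curve.
#'
#' @param detections tibble with `image_id`, box columns, `label`, `score`.
#' @param ground_truth tibble with `image_id`, box columns, `label`.
#' @param class class name to evaluate (`"benign"` or `"malignant"`).
#' @param iou_threshold match threshold (default 0.5).
#' @return AP in `[0, 1]`, or `NA` (with a warning) when the class has no
#'   ground truth.
#' @export
average_precision_50 <- function(detections, ground_truth, class,
                                 iou_threshold = 0.5) {
  gt <- ground_truth[ground_truth$label == class, ]
  if (!nrow(gt)) {
    warning("no ground truth for class '", class, "'; AP undefined")
    return(NA_real_)
  }
  det <- detections[detections$label == class, ]
  envelope_ap(pr_points(det, gt, iou_threshold))
}

#' @rdname average_precision_50
#' @return `map50()`: the unweighted mean AP over the two lesion classes
#'   (classes without ground truth are excluded with a warning).
#' @export
map50 <- function(detections, ground_truth, iou_threshold = 0.5) {
  aps <- vapply(VOC_CLASSES, function(cl)
    average_precision_50(detections, ground_truth, cl, iou_threshold),
    numeric(1))
  mean(aps, na.rm = TRUE)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the distinct scores; tied scores move along the
#' curve together, so the trapezoidal area equals the normalized
#' Mann-Whitney U statistic with ties counted one half.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return A list with `points` (tibble `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc requires both classes to be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- c(0, cumsum(y)[last] / n_pos)
  fpr <- c(0, cumsum(!y)[last] / n_neg)
  auc <- sum((fpr[-1] - fpr[-length(fpr)]) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = tibble::tibble(threshold = c(Inf, s[last]), fpr = fpr,
                               tpr = tpr),
       auc = auc)
}

#' Lesion-level confusion tally
#'
#' A malignant ground-truth lesion is a TP when at least one retained
#' malignant detection on any of its slices overlaps its box at
#' IoU >= `iou_threshold`, else an FN. A benign ground-truth lesion with
#' such an overlapping malignant detection is an FP, without one a TN.
#' Retained malignant detections overlapping no ground truth at all count
#' FP, capped at one per image per cluster of mutually overlapping boxes.
#'
#' @param detections retained detections tibble (`image_id`, box columns,
#'   `label`, `score`).
#' @param ground_truth tibble with `image_id`, box columns, `label`,
#'   `lesion_id` (one row per lesion per slice).
#' @param iou_threshold match threshold (default 0.5).
#' @return A one-row tibble: `TP`, `FP`, `TN`, `FN`.
#' @export
lesion_level_tally <- function(detections, ground_truth,
                               iou_threshold = 0.5) {
  known <- unique(ground_truth$image_id)
  if (nrow(detections) && !all(detections$image_id %in% known))
    stop("detection references unknown image: ",
         paste(setdiff(detections$image_id, known), collapse = ", "))
  mal_det <- detections[detections$label == "malignant", ]
  hit_by_lesion <- function(lid) {
    rows <- ground_truth[ground_truth$lesion_id == lid, ]
    for (i in seq_len(nrow(rows))) {
      d <- mal_det[mal_det$image_id == rows$image_id[i], ]
      if (nrow(d) && any(iou_matrix(d, rows[i, ]) >= iou_threshold))
        return(TRUE)
    }
    FALSE
  }
  lesions <- unique(ground_truth[, c("lesion_id", "label")])
  hits <- vapply(lesions$lesion_id, hit_by_lesion, logical(1))
  TP <- sum(hits & lesions$label == "malignant")
  FN <- sum(!hits & lesions$label == "malignant")
  FP <- sum(hits & lesions$label == "benign")
  TN <- sum(!hits & lesions$label == "benign")
  # malignant detections overlapping no ground truth at all
  if (nrow(mal_det)) {
    overlaps_gt <- vapply(seq_len(nrow(mal_det)), function(i) {
      g <- ground_truth[ground_truth$image_id == mal_det$image_id[i], ]
      nrow(g) > 0 && any(iou_matrix(mal_det[i, ], g) >= iou_threshold)
    }, logical(1))
    stray <- mal_det[!overlaps_gt, ]
    for (img in unique(stray$image_id)) {
      m <- box_matrix(stray[stray$image_id == img, ])
      FP <- FP + n_box_clusters(m)
    }
  }
  tibble::tibble(TP = TP, FP = FP, TN = TN, FN = FN)
}

# number of connected components under "IoU > 0" adjacency
n_box_clusters <- function(m) {
  n <- nrow(m)
  if (n == 1) return(1L)
  adj <- iou_matrix(m, m) > 0
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  length(unique(comp))
}
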