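# Model construction and training. Training follows the published recipe:
# batch size 1, SGD with momentum 0.9 and weight decay 5e-4, target
# assignment at IoU 0.5, 300 proposal candidates, 128 sampled anchors and
# 128 sampled ROIs per image with a 1:1 positive cap. Ground-truth boxes
# are appended to the proposal set during training so the second stage sees
# positives from the first epoch onward. The best-on-validation parameters
# are restored when training finishes.

#' Initialize a BC R-CNN model
#'
#' @param config a [bc_config()].
#' @return An object of class `bc_rcnn_model`: configuration, a flat named
#'   list of parameter arrays, and (after training) a loss history.
#' @export
bc_model <- function(config = bc_config()) {
  set.seed(config$seed)
  layout <- backbone_layout(config$backbone_preset)
  channels <- if (config$use_fpn) layout$fpn_channels else
    vapply(layout$stages, function(v) v[length(v)], 1)[4]
  n_shapes <- if (config$use_fpn) 2L * length(config$anchor_ratios) else
    length(config$anchor_scales) * length(config$anchor_ratios)
  params <- c(init_backbone_params(config$backbone_preset, config$use_fpn),
              init_rpn_params(channels, n_shapes),
              init_head_params(channels, config$pooled_size, config$num_classes),
              init_pdn_params(channels, config$pooled_size, config$num_classes))
  structure(list(config = config, params = params, loss_history = NULL),
            class = "bc_rcnn_model")
}

#' @export
print.bc_rcnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1))
  cat(sprintf("<bc_rcnn_model> preset=%s fpn=%s parameters=%s trained_epochs=%d\n",
              x$config$backbone_preset, x$config$use_fpn,
              format(n_par, big.mark = ","),
              if (is.null(x$loss_history)) 0L else max(x$loss_history$epoch)))
  invisible(x)
}

# feature levels for the three consumers (RPN, ROI head, PDN)
model_levels <- function(model, bb) {
  if (model$config$use_fpn) {
    fp <- fpn_forward(model, bb$stages)
    list(rpn = fp$levels, roi = fp$levels[c("P2", "P3", "P4", "P5")],
         pdn = fp$levels[c("P2", "P3", "P4")], fpn_caches = fp$caches)
  } else {
    term <- list(T16 = list(map = bb$terminal, stride = 16L))
    list(rpn = term, roi = term, pdn = term, fpn_caches = NULL)
  }
}

# refined boxes can collapse to slivers after clipping; give every box a
# minimum 2-px side (inside the image) before pooling
sanitize_for_pool <- function(m, width, height) {
  w <- m[, 3] - m[, 1]; h <- m[, 4] - m[, 2]
  cx <- pmin(pmax((m[, 1] + m[, 3]) / 2, 1), width - 1)
  cy <- pmin(pmax((m[, 2] + m[, 4]) / 2, 1), height - 1)
  w <- pmax(w, 2); h <- pmax(h, 2)
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

# One image: forward pass, loss, and (optionally) backward + gradients.
# Returns list(losses = bc_loss_breakdown, grads = named list | NULL).
bc_step <- function(model, image, gt_boxes, gt_labels, backward = TRUE) {
  cfg <- model$config
  image_size <- c(ncol(image), nrow(image))
  ge <- grad_env()
  bb <- backbone_forward(model, image)
  lv <- model_levels(model, bb)
  rpn_out <- rpn_forward(model, lv$rpn)

  # ---- RPN targets over the concatenated anchor set
  anchors <- do.call(rbind, lapply(rpn_out, function(o) box_matrix(o$anchors)))
  obj_logits <- unlist(lapply(rpn_out, `[[`, "objectness"), use.names = FALSE)
  delta_pred <- do.call(rbind, lapply(rpn_out, `[[`, "deltas"))
  asg <- rpn_assign(anchors, gt_boxes, cfg)
  smp <- sample_balanced(asg$labels, cfg$rpn_batch)
  samp <- c(smp$pos, smp$neg)
  n_samp <- length(samp)
  rpn_prob <- sigmoid(obj_logits[samp])
  rpn_lab <- asg$labels[samp]
  pos <- smp$pos
  rpn_dt <- if (length(pos))
    encode_deltas(anchors[pos, , drop = FALSE],
                  gt_boxes[asg$matched[pos], , drop = FALSE]) else NULL
  rpn_dp <- if (length(pos)) delta_pred[pos, , drop = FALSE] else NULL

  # ---- proposals (no gradient) + ground-truth boxes as extra candidates
  props <- propose(rpn_out, image_size, cfg)
  cand <- rbind(box_matrix(props), gt_boxes)
  rasg <- roi_assign(cand, gt_boxes, gt_labels, cfg)
  rsmp <- sample_balanced(ifelse(rasg$labels > 0L, 1, 0), cfg$roi_batch)
  ridx <- c(rsmp$pos, rsmp$neg)
  rois <- cand[ridx, , drop = FALSE]
  roi_lab <- rasg$labels[ridx]
  n_roi <- length(ridx)

  pool <- pool_rois(lv$roi, rois, cfg)
  head <- detection_head(model, pool$pooled)
  rpos <- which(roi_lab > 0L)
  roi_dt <- if (length(rpos))
    encode_deltas(rois[rpos, , drop = FALSE],
                  gt_boxes[rasg$matched[ridx][rpos], , drop = FALSE]) else NULL
  # predicted deltas at the target class slice
  roi_dp <- if (length(rpos)) {
    sel <- matrix(0, length(rpos), 4)
    for (q in 1:4)
      sel[, q] <- head$roi_deltas[cbind(rpos, 4L * roi_lab[rpos] + q)]
    sel
  } else NULL

  # ---- PDN on class-conditionally refined candidates (boxes detached);
  # a 64-candidate subsample per step bounds the extra-conv cost
  refined <- refine_rois(head, rois, image_size)
  rm_ref <- sanitize_for_pool(box_matrix(refined), image_size[1], image_size[2])
  if (backward && nrow(rm_ref) > 64L)
    rm_ref <- rm_ref[sample(nrow(rm_ref), 64L), , drop = FALSE]
  pasg <- roi_assign(rm_ref, gt_boxes, gt_labels, cfg)
  feats <- pdn_features(model, lv$pdn, rm_ref)
  pcls <- pdn_classify(model, feats$features)

  losses <- compute_losses(
    list(rpn_objectness = rpn_prob, rpn_deltas = rpn_dp,
         roi_scores = head$roi_scores, roi_deltas = roi_dp,
         pdn_scores = pcls$pdn_scores),
    list(rpn_labels = rpn_lab, rpn_delta_targets = rpn_dt,
         roi_labels = roi_lab, roi_delta_targets = roi_dt,
         pdn_labels = pasg$labels))
  if (!backward)
    return(list(losses = losses, grads = NULL))

  # ---- backward: PDN
  g_pdn_logits <- (pcls$pdn_scores -
    onehot(pasg$labels, cfg$num_classes)) / length(pasg$labels)
  g_feats <- pdn_classify_bw(pcls$cache, g_pdn_logits, ge)
  g_pooled_pdn <- pdn_features_bw(model, feats, g_feats, ge)
  g_lv <- pool_rois_bw(lv$pdn, feats$pool_cache, g_pooled_pdn, cfg)

  # ---- backward: detection head
  g_roi_logits <- (head$roi_scores - onehot(roi_lab, cfg$num_classes)) / n_roi
  g_roi_deltas <- matrix(0, n_roi, 4L * cfg$num_classes)
  if (length(rpos)) {
    gd <- smooth_l1_grad(roi_dp - roi_dt) / n_roi
    for (q in 1:4)
      g_roi_deltas[cbind(rpos, 4L * roi_lab[rpos] + q)] <- gd[, q]
  }
  g_pooled_roi <- detection_head_bw(head$cache, g_roi_logits, g_roi_deltas, ge)
  g_lv_roi <- pool_rois_bw(lv$roi, pool, g_pooled_roi, cfg)
  for (nm in names(g_lv_roi))
    if (!is.null(g_lv_roi[[nm]]))
      g_lv[[nm]] <- if (is.null(g_lv[[nm]])) g_lv_roi[[nm]] else
        g_lv[[nm]] + g_lv_roi[[nm]]

  # ---- backward: RPN
  g_obj_full <- numeric(length(obj_logits))
  g_obj_full[samp] <- (rpn_prob - rpn_lab) / n_samp
  g_delta_full <- matrix(0, nrow(anchors), 4)
  if (length(pos))
    g_delta_full[pos, ] <- smooth_l1_grad(rpn_dp - rpn_dt) / n_samp
  offset <- 0L
  g_levels_all <- g_lv
  for (nm in names(rpn_out)) {
    n_a <- length(rpn_out[[nm]]$objectness)
    sl <- offset + seq_len(n_a)
    g_map <- rpn_backward_level(rpn_out[[nm]]$cache, g_obj_full[sl],
                                g_delta_full[sl, , drop = FALSE], ge)
    key <- if (cfg$use_fpn) nm else "T16"
    g_levels_all[[key]] <- if (is.null(g_levels_all[[key]])) g_map else
      g_levels_all[[key]] + g_map
    offset <- offset + n_a
  }

  # ---- backward: pyramid and backbone
  if (cfg$use_fpn) {
    g_stages <- fpn_backward(model, lv$fpn_caches, g_levels_all, ge)
    backbone_backward(model, bb$caches, g_stages, ge)
  } else {
    backbone_backward(model, bb$caches, list(S4 = g_levels_all$T16), ge)
  }
  list(losses = losses, grads = grad_list(ge))
}

onehot <- function(labels0, K) {
  m <- matrix(0, length(labels0), K)
  m[cbind(seq_along(labels0), labels0 + 1L)] <- 1
  m
}

# Load a VOC split into memory, optionally applying the preprocessing chain
# (background subtraction, masking, rescale to config$short_side).
load_detection_dataset <- function(dir, split, config, preprocess = TRUE) {
  ds <- voc_dataset(dir, split)
  purrr::map(seq_len(nrow(ds)), function(i) {
    img <- read_image(ds$image_path[i])
    rec <- read_voc_annotation(ds$annotation_path[i])
    scale <- 1
    if (preprocess) {
      pp <- preprocess_image(img, target = config$short_side)
      img <- pp$image; scale <- pp$scale
    }
    ann <- rec$annotations
    gt <- if (nrow(ann)) box_matrix(ann) * scale else
      matrix(numeric(), 0, 4)
    list(image_id = ds$image_id[i], image = img, plane = rec$plane,
         gt_boxes = gt,
         gt_labels = if (nrow(ann)) match(ann$label, VOC_CLASSES) else integer(),
         lesion_id = if (nrow(ann)) ann$lesion_id else character())
  })
}

#' Train a BC R-CNN model
#'
#' SGD with momentum on the five-term composite loss; per-epoch mean
#' breakdown on the training split and mean total loss on the validation
#' split are recorded, and the best-on-validation parameters are restored
#' at the end. Fully seeded: two runs with the same configuration and data
#' produce identical loss histories.
#'
#' @param data_dir VOC2007 dataset root with `train`/`val` splits.
#' @param config a [bc_config()].
#' @param preprocess apply the preprocessing chain when loading.
#' @return A trained `bc_rcnn_model` with a `loss_history` tibble (columns
#'   `epoch`, the five loss terms, `total`, `val_total`).
#' @export
bc_train <- function(data_dir, config = bc_config(), preprocess = TRUE) {
  train <- load_detection_dataset(data_dir, "train", config, preprocess)
  if (!length(train)) stop("empty training split")
  val <- tryCatch(load_detection_dataset(data_dir, "val", config, preprocess),
                  error = function(e) list())
  model <- bc_model(config)
  opt <- sgd_init(model$params)
  history <- NULL
  best_val <- Inf
  best_params <- model$params
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(train))
    ep <- NULL
    for (i in ord) {
      r <- train[[i]]
      st <- bc_step(model, r$image, r$gt_boxes, r$gt_labels, backward = TRUE)
      grads <- clip_grad_norm(st$grads, config$grad_clip)
      model$params <- sgd_step(model$params, grads, opt,
                               config$learning_rate, config$momentum,
                               config$weight_decay)
      ep <- dplyr::bind_rows(ep, st$losses)
    }
    row <- dplyr::summarise(ep, dplyr::across(dplyr::everything(), mean))
    row$epoch <- epoch
    if (length(val)) {
      vt <- vapply(val, function(r)
        bc_step(model, r$image, r$gt_boxes, r$gt_labels,
                backward = FALSE)$losses$total, numeric(1))
      row$val_total <- mean(vt)
      if (row$val_total < best_val) {
        best_val <- row$val_total
        best_params <- model$params
      }
    } else row$val_total <- NA_real_
    history <- dplyr::bind_rows(history, row)
    bc_log("epoch", sprintf("%d train_total=%.4f val_total=%.4f",
                            epoch, row$total, row$val_total))
  }
  if (is.finite(best_val)) model$params <- best_params
  model$loss_history <- dplyr::relocate(history, "epoch")
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a flat named-array container (the parameter list) plus
#' the configuration echo and loss history.
#'
#' @param model a `bc_rcnn_model`.
#' @param path checkpoint file.
#' @return `bc_save_checkpoint()`: `path` invisibly;
#'   `bc_load_checkpoint()`: the restored model.
#' @export
bc_save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, config = unclass(model$config),
               loss_history = model$loss_history), path)
  invisible(path)
}

#' @rdname bc_save_checkpoint
#' @export
bc_load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = bc_config(x$config), params = x$params,
                 loss_history = x$loss_history),
            class = "bc_rcnn_model")
}
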