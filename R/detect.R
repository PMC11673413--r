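# Inference: proposals from the RPN, class-conditional refinement, PDN
# classification, retention at the 0.5 score threshold, and class-wise NMS.
# Slice-level scores are the maxima of the PDN class probabilities over all
# candidates, giving each slice a benign and a malignant possibility score.

#' Detect lesions in one slice
#'
#' @param model a trained `bc_rcnn_model`.
#' @param image preprocessed numeric matrix.
#' @param image_id identifier copied into the output.
#' @param plane slice orientation label.
#' @return A tibble of retained detections: `image_id`, `plane`, box
#'   columns, `label` (`"benign"`/`"malignant"`), `score` (the PDN score of
#'   the detection's own class), `malignant_score`. Slice-level scores are
#'   attached as attribute `slice` (one-row tibble with `benign_score`,
#'   `malignant_score`, `slice_malignant`).
#' @export
bc_detect <- function(model, image, image_id = "slice", plane = "axial") {
  cfg <- model$config
  image_size <- c(ncol(image), nrow(image))
  bb <- backbone_forward(model, image)
  lv <- model_levels(model, bb)
  rpn_out <- rpn_forward(model, lv$rpn)
  props <- propose(rpn_out, image_size, cfg)
  pool <- pool_rois(lv$roi, props, cfg)
  head <- detection_head(model, pool$pooled)
  refined <- refine_rois(head, props, image_size)
  rm_ref <- sanitize_for_pool(box_matrix(refined), image_size[1], image_size[2])
  feats <- pdn_features(model, lv$pdn, rm_ref)
  pcls <- pdn_classify(model, feats$features)

  slice <- tibble::tibble(
    image_id = image_id, plane = plane,
    benign_score = max(pcls$pdn_scores[, 2]),
    malignant_score = max(pcls$pdn_scores[, 3]))
  slice$slice_malignant <- any(pcls$retained & pcls$final_label == 2L)

  keep <- which(pcls$retained)
  det <- tibble::tibble(image_id = character(), plane = character(),
                        x_min = numeric(), y_min = numeric(),
                        x_max = numeric(), y_max = numeric(),
                        label = character(), score = numeric(),
                        malignant_score = numeric())
  if (length(keep)) {
    m <- rm_ref[keep, , drop = FALSE]
    lab <- pcls$final_label[keep]
    sc <- pcls$pdn_scores[cbind(keep, lab + 1L)]
    kept <- integer()
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      kk <- nms(m[idx, , drop = FALSE], sc[idx], cfg$detect_nms_threshold)
      kept <- c(kept, idx[kk])
    }
    kept <- kept[order(sc[kept], decreasing = TRUE)]
    det <- tibble::tibble(
      image_id = image_id, plane = plane,
      x_min = m[kept, 1], y_min = m[kept, 2],
      x_max = m[kept, 3], y_max = m[kept, 4],
      label = VOC_CLASSES[lab[kept]], score = sc[kept],
      malignant_score = pcls$pdn_scores[keep[kept], 3])
  }
  attr(det, "slice") <- slice
  det
}

#' Detect lesions over a VOC dataset split
#'
#' @param model a trained `bc_rcnn_model`.
#' @param data_dir VOC2007 dataset root.
#' @param split `"train"`, `"val"`, or `"test"`.
#' @param preprocess apply the preprocessing chain when loading.
#' @return A list with `detections` (tibble over all images) and `slices`
#'   (one row per image: `benign_score`, `malignant_score`,
#'   `slice_malignant`).
#' @export
bc_detect_dataset <- function(model, data_dir, split = "test",
                              preprocess = TRUE) {
  recs <- load_detection_dataset(data_dir, split, model$config, preprocess)
  dets <- NULL; slices <- NULL
  for (r in recs) {
    d <- bc_detect(model, r$image, image_id = r$image_id, plane = r$plane)
    dets <- dplyr::bind_rows(dets, d)
    slices <- dplyr::bind_rows(slices, attr(d, "slice"))
  }
  if (is.null(dets)) dets <- tibble::tibble()
  list(detections = dets, slices = slices)
}
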