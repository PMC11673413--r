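# End-to-end evaluation on a phantom dataset: detection AP, slice-level
# ROC/AUC, lesion-level sensitivity and false-positive rate, and 3D
# quadrant/laterality accuracy against the generator's ground truth.

# ground truth for a split, in the (possibly rescaled) evaluation frame
load_ground_truth <- function(data_dir, split, config, preprocess = TRUE) {
  recs <- load_detection_dataset(data_dir, split, config, preprocess)
  purrr::map_dfr(recs, function(r) {
    if (!nrow(matrix(r$gt_boxes, ncol = 4))) return(NULL)
    b <- box_tibble(r$gt_boxes)
    b$image_id <- r$image_id
    b$plane <- r$plane
    b$label <- VOC_CLASSES[r$gt_labels]
    b$lesion_id <- r$lesion_id
    b
  })
}

scale_geometry <- function(g, s) {
  bc_geometry(Y_mid = g$Y_mid * s, x_Rmid = g$x_Rmid * s,
              x_Lmid = g$x_Lmid * s, x_mid = g$x_mid * s,
              axial_baseline = g$axial_baseline * s,
              sag_height = g$sag_height * s,
              y_orientation = g$y_orientation)
}

# best retained detection for a lesion on one plane (IoU >= threshold)
match_lesion_detection <- function(dets, gt_row, iou_threshold = 0.5) {
  d <- dets[dets$image_id == gt_row$image_id, ]
  if (!nrow(d)) return(NULL)
  ious <- iou_matrix(d, gt_row)[, 1]
  d <- d[ious >= iou_threshold, ]
  if (!nrow(d)) return(NULL)
  d[which.max(d$score), ]
}

#' Evaluate a trained model on a phantom dataset split
#'
#' Runs detection over the split and scores it against the generator's
#' ground truth: mAP50 and per-class AP, slice-level benign/malignant
#' ROC AUC (slice score = maximum PDN malignant probability), lesion-level
#' sensitivity and false-positive rate, and — via dual-plane case reports —
#' quadrant and laterality accuracy over lesions detected in both planes.
#'
#' @param model a trained `bc_rcnn_model`.
#' @param data_dir phantom dataset root (as written by
#'   [generate_dataset()], including `manifest.csv` and `geometry.csv`).
#' @param split dataset split to evaluate (default `"test"`).
#' @param preprocess apply the preprocessing chain when loading.
#' @return A list: `metrics` (one-row tibble), `tally` (lesion confusion
#'   counts), `detections`, `slices`, `reports` (per-lesion case reports
#'   joined with ground truth).
#' @export
bc_evaluate_phantom <- function(model, data_dir, split = "test",
                                preprocess = TRUE) {
  cfg <- model$config
  out <- bc_detect_dataset(model, data_dir, split, preprocess)
  gt <- load_ground_truth(data_dir, split, cfg, preprocess)
  ap_b <- average_precision_50(out$detections, gt, "benign")
  ap_m <- average_precision_50(out$detections, gt, "malignant")

  slice_truth <- dplyr::summarise(
    dplyr::group_by(gt, .data$image_id),
    has_malignant = any(.data$label == "malignant"), .groups = "drop")
  slices <- dplyr::left_join(out$slices, slice_truth, by = "image_id")
  slices$has_malignant[is.na(slices$has_malignant)] <- FALSE
  auc <- roc_auc(slices$malignant_score, slices$has_malignant)$auc

  tally <- lesion_level_tally(out$detections, gt)
  rates <- suppressWarnings(confusion_rates(tally))

  manifest <- read.csv(file.path(data_dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  geo <- read.csv(file.path(data_dir, "geometry.csv"))
  truth <- unique(manifest[manifest$split == split,
                           c("case", "lesion_id", "label", "quadrant", "laterality")])
  # geometry is stated in the generator frame; rescale to the evaluation frame
  s <- if (preprocess) cfg$short_side / min(dim(read_image(
    voc_dataset(data_dir)$image_path[1]))) else 1
  reports <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    lid <- truth$lesion_id[i]
    g <- scale_geometry(row_to_geometry(geo[geo$case == truth$case[i], ]), s)
    gt_l <- gt[gt$lesion_id == lid, ]
    ax <- gt_l[gt_l$plane == "axial", ]
    sg <- gt_l[gt_l$plane == "sagittal", ]
    rep <- build_case_report(
      lid,
      if (nrow(ax)) match_lesion_detection(out$detections, ax[1, ]) else NULL,
      if (nrow(sg)) match_lesion_detection(out$detections, sg[1, ]) else NULL,
      g, cfg$malignant_threshold)
    rep$true_label <- truth$label[i]
    rep$true_quadrant <- truth$quadrant[i]
    rep$true_laterality <- truth$laterality[i]
    rep
  })
  both <- reports[!is.na(reports$quadrant), ]
  metrics <- tibble::tibble(
    map50 = mean(c(ap_b, ap_m), na.rm = TRUE),
    ap_benign = ap_b, ap_malignant = ap_m, auc = auc,
    sensitivity = rates$sensitivity, fpr = rates$fpr,
    quadrant_accuracy = if (nrow(both))
      mean(both$quadrant == both$true_quadrant) else NA_real_,
    laterality_accuracy = if (nrow(both))
      mean(both$laterality == both$true_laterality) else NA_real_,
    n_lesions = nrow(reports), n_located = nrow(both))
  list(metrics = metrics, tally = tally, detections = out$detections,
       slices = slices, reports = reports)
}
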