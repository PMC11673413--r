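# Precise deep network (PDN): the diagnosis stage. The first-stage class
# scores are treated as intermediate results: each candidate is refined with
# the regression deltas of its argmax class, re-pooled from the pyramid
# levels P2-P4 chosen by refined-ROI size (< 64 px, 64-128 px, > 128 px),
# passed through three extra 3x3 convolutional layers that share no weights
# with the backbone or detection head, and classified by a final fully
# connected layer into background / benign / malignant.

#' Class-conditional ROI refinement
#'
#' For each candidate the class index with the highest first-stage score is
#' selected (ties toward the lower index); its four regression parameters
#' are decoded against the proposal and clipped to the image. Background
#' candidates keep their proposal box unchanged.
#'
#' @param head_out a [detection_head()] result (`roi_scores`, `roi_deltas`).
#' @param proposals proposal boxes (tibble or matrix).
#' @param image_size integer `c(width, height)`.
#' @return A tibble with refined box columns, `first_label` (0 = background,
#'   1 = benign, 2 = malignant), and `first_score`.
#' @export
refine_rois <- function(head_out, proposals, image_size) {
  scores <- head_out$roi_scores
  deltas <- head_out$roi_deltas
  m <- box_matrix(proposals)
  n <- nrow(m)
  stopifnot(nrow(scores) == n, ncol(deltas) == 4L * ncol(scores))
  cls <- row_argmax(scores) - 1L # 0-based class index
  sel <- matrix(0, n, 4L)
  for (q in 1:4) sel[, q] <- deltas[cbind(seq_len(n), 4L * cls + q)]
  refined <- box_matrix(decode_deltas(m, sel, width = image_size[1],
                                      height = image_size[2]))
  bg <- cls == 0L
  refined[bg, ] <- m[bg, , drop = FALSE]
  out <- box_tibble(refined)
  out$first_label <- cls
  out$first_score <- scores[cbind(seq_len(n), cls + 1L)]
  out
}

#' Assign a refined ROI to a PDN pyramid level
#'
#' Size is `sqrt(w * h)`: below 64 px maps to P2, 64-128 px (inclusive) to
#' P3, above 128 px to P4.
#'
#' @param b boxes (tibble, matrix, or length-4 vector).
#' @return Integer vector of levels in `2..4`.
#' @export
assign_pdn_level <- function(b) {
  m <- box_matrix(b)
  size <- sqrt((m[, 3] - m[, 1]) * (m[, 4] - m[, 2]))
  if (any(size <= 0)) stop("zero-area box cannot be assigned a level")
  ifelse(size < 64, 2L, ifelse(size <= 128, 3L, 4L))
}

init_pdn_params <- function(channels, pooled_size, K, n_conv = 3L) {
  params <- list()
  for (i in seq_len(n_conv)) {
    params[[sprintf("pdn.c%d.w", i)]] <- he_conv(3, 3, channels, channels)
    params[[sprintf("pdn.c%d.b", i)]] <- numeric(channels)
  }
  params[["pdn.fc.w"]] <- matrix(rnorm(channels * pooled_size^2 * K, sd = 0.01),
                                 channels * pooled_size^2, K)
  params[["pdn.fc.b"]] <- numeric(K)
  params
}

#' PDN deep feature extraction
#'
#' Re-pools each refined box to 7x7 with ROI alignment from its assigned
#' pyramid level (P2-P4; the terminal map in single-level mode), then applies
#' three channel-preserving 3x3 convolutions with ReLU. The refined box
#' coordinates are treated as constants: gradients flow through the PDN
#' branch into the feature maps, not into the box regression.
#'
#' @param model a `bc_rcnn_model`.
#' @param levels named feature levels (`P2`..; or a single terminal level).
#' @param refined refined boxes (tibble or matrix).
#' @return A list with `features` (`[P, P, C, n]`), `pool_cache`, `caches`.
#' @export
pdn_features <- function(model, levels, refined) {
  cfg <- model$config
  m <- box_matrix(refined)
  level_assign <- if (length(levels) == 1L) rep(1L, nrow(m)) else
    match(paste0("P", assign_pdn_level(m)), names(levels))
  pool <- pool_rois(levels, m, cfg, level_assign = level_assign)
  x <- pool$pooled
  caches <- vector("list", 3L)
  for (i in 1:3) {
    y <- conv2d_stack_fw(x, model$params[[sprintf("pdn.c%d.w", i)]],
                         model$params[[sprintf("pdn.c%d.b", i)]])
    mask <- y > 0
    caches[[i]] <- list(x = x, mask = mask)
    x <- y * mask
  }
  list(features = x, pool_cache = pool, caches = caches)
}

# backward through the PDN conv stack; returns gradient on the pooled array
pdn_features_bw <- function(model, feat_out, g_features, ge) {
  g <- g_features
  for (i in 3:1) {
    cc <- feat_out$caches[[i]]
    g <- g * cc$mask
    bw <- conv2d_stack_bw(cc$x, model$params[[sprintf("pdn.c%d.w", i)]], g)
    grad_add(ge, sprintf("pdn.c%d.w", i), bw$gw)
    grad_add(ge, sprintf("pdn.c%d.b", i), bw$gb)
    g <- bw$gx
  }
  g
}

#' PDN classification
#'
#' One fully connected layer with softmax over background/benign/malignant.
#' A candidate is a retained detection when its argmax class is a lesion
#' class and that class's score strictly exceeds `malignant_threshold`
#' (default 0.5; the same retention rule is applied to benign candidates).
#'
#' @param model a `bc_rcnn_model`.
#' @param features PDN deep features (`[P, P, C, n]`).
#' @return A list with `pdn_scores` (`n x K`), `final_label` (0-based),
#'   `retained` (logical), `logits`, and caches.
#' @export
pdn_classify <- function(model, features) {
  flat <- flatten_pooled(features)
  fc <- linear_fw(flat, model$params[["pdn.fc.w"]], model$params[["pdn.fc.b"]])
  scores <- softmax_rows(fc$y)
  final <- row_argmax(scores) - 1L
  own <- scores[cbind(seq_along(final), final + 1L)]
  retained <- final > 0L & own > model$config$malignant_threshold
  list(pdn_scores = scores, final_label = final, retained = retained,
       logits = fc$y, cache = list(fc = fc, fdim = dim(features)))
}

pdn_classify_bw <- function(cache, g_logits, ge) {
  bw <- linear_bw(cache$fc, g_logits)
  grad_add(ge, "pdn.fc.w", bw$gw); grad_add(ge, "pdn.fc.b", bw$gb)
  unflatten_pooled(bw$gx, cache$fdim)
}

#' Dual-plane lesion diagnosis fusion
#'
#' A lesion is malignant when either plane calls it malignant; benign when
#' at least one plane detected it and neither called it malignant;
#' undetected when absent from both planes.
#'
#' @param axial_malignant,sagittal_malignant logical vectors (one element
#'   per lesion); `NA` means the lesion was not detected in that plane.
#' @return Character vector: `"malignant"`, `"benign"`, or `"undetected"`.
#' @examples
#' fuse_dual_plane(c(TRUE, FALSE, NA), c(FALSE, FALSE, NA))
#' @export
fuse_dual_plane <- function(axial_malignant, sagittal_malignant) {
  stopifnot(length(axial_malignant) == length(sagittal_malignant))
  undetected <- is.na(axial_malignant) & is.na(sagittal_malignant)
  mal <- isTRUE_vec(axial_malignant) | isTRUE_vec(sagittal_malignant)
  out <- ifelse(mal, "malignant", "benign")
  out[undetected] <- "undetected"
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
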