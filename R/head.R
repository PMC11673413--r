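# ROI feature extraction and the first-stage detection head. ROIs are
# assigned to pyramid levels with the canonical-size rule (canonical ROI
# size 160, k0 = 4), pooled to 7x7 with quantization-free ROI alignment
# (2x2 bilinear samples per bin), and classified/regressed by two parallel
# fully connected layers: one emitting 4K class-conditional deltas, one
# emitting K class scores.

#' Assign a box to a feature pyramid level
#'
#' `k = clamp(floor(k0 + log2(sqrt(w * h) / canonical_size)), 2, 5)`, with
#' the canonical ROI size reduced to 160.
#'
#' @param b boxes (tibble, matrix, or length-4 vector).
#' @param canonical_size canonical ROI size in pixels (default 160).
#' @param k0 level a canonical-size box maps to (default 4).
#' @return Integer vector of levels in `2..5`.
#' @export
assign_fpn_level <- function(b, canonical_size = 160L, k0 = 4L) {
  m <- box_matrix(b)
  area <- (m[, 3] - m[, 1]) * (m[, 4] - m[, 2])
  if (any(area <= 0)) stop("zero-area box cannot be assigned a level")
  pmin(pmax(floor(k0 + log2(sqrt(area) / canonical_size)), 2L), 5L)
}

#' Quantization-free ROI pooling (ROI align)
#'
#' Divides each image-coordinate box into `pooled_size^2` bins on the
#' feature map (no coordinate rounding anywhere) and averages 2x2 regularly
#' spaced bilinear samples per bin. Feature-map pixel centers sit at
#' `(index + 0.5) * stride` in image coordinates.
#'
#' @param feature numeric `[H, W, C]` array.
#' @param stride feature-map stride in image pixels.
#' @param b boxes in image coordinates.
#' @param pooled_size output bins per side (default 7).
#' @param sampling bilinear samples per bin side (default 2).
#' @return A `[pooled, pooled, C, n]` array.
#' @export
roi_align <- function(feature, stride, b, pooled_size = 7L, sampling = 2L) {
  m <- box_matrix(b)
  if (any((m[, 3] - m[, 1]) <= 0 | (m[, 4] - m[, 2]) <= 0))
    stop("roi_align requires boxes with positive area")
  H <- dim(feature)[1]; W <- dim(feature)[2]
  if (any(m[, 1] / stride >= W | m[, 3] / stride <= 0 |
          m[, 2] / stride >= H | m[, 4] / stride <= 0))
    stop("box lies fully outside the feature map")
  roi_align_fw(feature, m, stride, as.integer(pooled_size),
               as.integer(sampling))
}

# Pool a set of boxes from a pyramid (or single level), grouping by assigned
# level. Returns pooled [P, P, C, n] plus the per-roi level for backward.
pool_rois <- function(levels, b, config, level_assign = NULL) {
  m <- box_matrix(b)
  n <- nrow(m)
  if (is.null(level_assign)) {
    if (length(levels) == 1L) level_assign <- rep(1L, n)
    else {
      lv <- assign_fpn_level(m, config$canonical_roi_size)
      level_assign <- match(paste0("P", lv), names(levels))
    }
  }
  C <- dim(levels[[1]]$map)[3]
  P <- config$pooled_size
  out <- array(0, c(P, P, C, n))
  for (li in unique(level_assign)) {
    idx <- which(level_assign == li)
    out[, , , idx] <- roi_align(levels[[li]]$map, levels[[li]]$stride,
                                m[idx, , drop = FALSE], P, 2L)
  }
  list(pooled = out, level_assign = level_assign, boxes = m)
}

# scatter pooled-feature gradients back to the levels; returns a named list
# of per-level gradient arrays (NULL where untouched)
pool_rois_bw <- function(levels, pool_cache, g_pooled, config) {
  g_levels <- setNames(vector("list", length(levels)), names(levels))
  for (li in unique(pool_cache$level_assign)) {
    idx <- which(pool_cache$level_assign == li)
    g <- roi_align_bw(g_pooled[, , , idx, drop = FALSE],
                      pool_cache$boxes[idx, , drop = FALSE],
                      levels[[li]]$stride, config$pooled_size, 2L,
                      dim(levels[[li]]$map))
    g_levels[[li]] <- if (is.null(g_levels[[li]])) g else g_levels[[li]] + g
  }
  g_levels
}

init_head_params <- function(channels, pooled_size, K) {
  n_in <- channels * pooled_size^2
  list("head.reg.w" = matrix(rnorm(n_in * 4 * K, sd = 0.001), n_in, 4L * K),
       "head.reg.b" = numeric(4L * K),
       "head.cls.w" = matrix(rnorm(n_in * K, sd = 0.01), n_in, K),
       "head.cls.b" = numeric(K))
}

# flatten pooled [P,P,C,n] to [n, P*P*C]
flatten_pooled <- function(pooled) {
  n <- dim(pooled)[4]
  t(matrix(pooled, ncol = n))
}

unflatten_pooled <- function(flat, pdim) {
  array(t(flat), pdim)
}

#' First-stage detection head
#'
#' Two parallel fully connected layers on the flattened pooled features:
#' regression deltas (`n x 4K`, class-conditional) and softmax class scores
#' (`n x K`).
#'
#' @param model a `bc_rcnn_model`.
#' @param pooled `[P, P, C, n]` array from [roi_align()]/proposal pooling.
#' @return A list with `roi_scores` (`n x K`, rows sum to 1), `roi_deltas`
#'   (`n x 4K`), `logits`, and caches.
#' @export
detection_head <- function(model, pooled) {
  flat <- flatten_pooled(pooled)
  reg <- linear_fw(flat, model$params[["head.reg.w"]], model$params[["head.reg.b"]])
  cls <- linear_fw(flat, model$params[["head.cls.w"]], model$params[["head.cls.b"]])
  list(roi_scores = softmax_rows(cls$y), roi_deltas = reg$y,
       logits = cls$y, cache = list(reg = reg, cls = cls, pdim = dim(pooled)))
}

# returns gradient on the pooled array
detection_head_bw <- function(cache, g_logits, g_deltas, ge) {
  bw_cls <- linear_bw(cache$cls, g_logits)
  bw_reg <- linear_bw(cache$reg, g_deltas)
  grad_add(ge, "head.cls.w", bw_cls$gw); grad_add(ge, "head.cls.b", bw_cls$gb)
  grad_add(ge, "head.reg.w", bw_reg$gw); grad_add(ge, "head.reg.b", bw_reg$gb)
  unflatten_pooled(bw_cls$gx + bw_reg$gx, cache$pdim)
}
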