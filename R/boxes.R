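# Box geometry. Boxes are axis-aligned rectangles in continuous, 0-based,
# half-open image coordinates [x_min, x_max) x [y_min, y_max); x runs right,
# y runs down, origin at the top-left image corner. User-facing functions
# accept and return tibbles with columns x_min, y_min, x_max, y_max; internal
# numeric work uses plain 4-column matrices.

BOX_COLS <- c("x_min", "y_min", "x_max", "y_max")

#' Build a box tibble
#'
#' @param x_min,y_min,x_max,y_max numeric vectors of corner coordinates in the
#'   continuous 0-based half-open convention.
#' @return A tibble with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' boxes(0, 0, 10, 20)
#' @export
boxes <- function(x_min, y_min, x_max, y_max) {
  b <- tibble::tibble(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                      x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_boxes(b)
  b
}

validate_boxes <- function(b) {
  m <- box_matrix(b)
  if (any(!is.finite(m))) stop("box coordinates must be finite")
  if (any(m[, 3] < m[, 1]) || any(m[, 4] < m[, 2]))
    stop("boxes must satisfy x_max >= x_min and y_max >= y_min")
  invisible(b)
}

# Accepts a tibble/data.frame with the box columns, a 4-column matrix, or a
# length-4 numeric vector; returns an n x 4 matrix.
box_matrix <- function(b) {
  if (is.matrix(b)) {
    stopifnot(ncol(b) == 4)
    return(unname(b))
  }
  if (is.data.frame(b)) return(unname(as.matrix(b[BOX_COLS])))
  if (is.numeric(b) && length(b) == 4) return(matrix(b, 1))
  stop("cannot interpret object as boxes")
}

box_tibble <- function(m) {
  tibble::tibble(x_min = m[, 1], y_min = m[, 2], x_max = m[, 3], y_max = m[, 4])
}

#' Intersection over union of two boxes
#'
#' Areas follow the half-open convention, so a box's area is
#' `(x_max - x_min) * (y_max - y_min)`. Disjoint boxes score 0.
#'
#' @param a,b single boxes (length-4 vectors, 1-row tibbles) for `iou()`;
#'   box sets for `iou_matrix()`.
#' @return `iou()`: a scalar in \[0, 1\]. `iou_matrix()`: an
#'   `nrow(a) x nrow(b)` matrix.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 5, 15, 15)) # 25 / 175
#' @export
iou <- function(a, b) {
  iou_matrix_cpp(box_matrix(a), box_matrix(b))[1, 1]
}

#' @rdname iou
#' @export
iou_matrix <- function(a, b) {
  iou_matrix_cpp(box_matrix(a), box_matrix(b))
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in descending score order; a box is suppressed when its
#' IoU with an already-kept box exceeds `threshold`. Score ties are broken
#' toward the earlier row.
#'
#' @param b boxes (tibble or matrix).
#' @param scores numeric vector, one score per box.
#' @param threshold IoU above which a lower-scored box is suppressed.
#' @return Integer indices of kept boxes, in descending score order.
#' @export
nms <- function(b, scores, threshold) {
  m <- box_matrix(b)
  stopifnot(length(scores) == nrow(m), threshold >= 0, threshold <= 1)
  as.integer(nms_cpp(m, as.numeric(scores), threshold))
}

#' Clip boxes to image bounds
#'
#' @param b boxes (tibble or matrix).
#' @param width,height image size in pixels.
#' @return Boxes of the same form, intersected with `[0, width] x [0, height]`.
#' @export
clip_boxes <- function(b, width, height) {
  m <- box_matrix(b)
  m[, 1] <- pmin(pmax(m[, 1], 0), width)
  m[, 3] <- pmin(pmax(m[, 3], 0), width)
  m[, 2] <- pmin(pmax(m[, 2], 0), height)
  m[, 4] <- pmin(pmax(m[, 4], 0), height)
  if (is.data.frame(b)) {
    b[BOX_COLS] <- box_tibble(m)
    b
  } else m
}

#' Box regression parameterization
#'
#' The standard two-shift/two-scale encoding used by both bounding-box
#' regression passes: `tx = (cx_t - cx_a) / w_a`, `ty = (cy_t - cy_a) / h_a`,
#' `tw = log(w_t / w_a)`, `th = log(h_t / h_a)`. `decode_deltas()` is the
#' exact inverse; decoded boxes are clipped to the image when `width` and
#' `height` are given.
#'
#' @param anchors,targets box sets of equal row count.
#' @param deltas numeric `n x 4` matrix of (tx, ty, tw, th).
#' @param width,height optional image bounds for clipping.
#' @return `encode_deltas()`: an `n x 4` matrix. `decode_deltas()`: a box
#'   tibble.
#' @export
encode_deltas <- function(anchors, targets) {
  a <- box_matrix(anchors); t <- box_matrix(targets)
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  if (any(wa <= 0) || any(ha <= 0)) stop("anchors must have positive width and height")
  wt <- t[, 3] - t[, 1]; ht <- t[, 4] - t[, 2]
  cbind((((t[, 1] + t[, 3]) / 2) - ((a[, 1] + a[, 3]) / 2)) / wa,
        (((t[, 2] + t[, 4]) / 2) - ((a[, 2] + a[, 4]) / 2)) / ha,
        log(wt / wa), log(ht / ha))
}

#' @rdname encode_deltas
#' @export
decode_deltas <- function(anchors, deltas, width = NULL, height = NULL) {
  a <- box_matrix(anchors)
  deltas <- matrix(deltas, ncol = 4)
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  if (any(wa <= 0) || any(ha <= 0)) stop("anchors must have positive width and height")
  cx <- (a[, 1] + a[, 3]) / 2 + deltas[, 1] * wa
  cy <- (a[, 2] + a[, 4]) / 2 + deltas[, 2] * ha
  # scale offsets are clamped (|log ratio| <= 20) to keep exp() finite for
  # untrained regression outputs; any practical encoding is far below this
  w <- wa * exp(pmin(pmax(deltas[, 3], -20), 20))
  h <- ha * exp(pmin(pmax(deltas[, 4], -20), 20))
  out <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  if (!is.null(width)) out <- clip_boxes(out, width, height)
  box_tibble(out)
}

#' Box center
#'
#' Arithmetic midpoint of the corners, as used by the 3D localization stage.
#'
#' @param b a single box (length-4 vector or 1-row tibble) or a box set.
#' @return A tibble with columns `x` and `y`, one row per box.
#' @examples
#' box_center(c(0, 0, 10, 20)) # (5, 10)
#' @export
box_center <- function(b) {
  m <- box_matrix(b)
  tibble::tibble(x = (m[, 1] + m[, 3]) / 2, y = (m[, 2] + m[, 4]) / 2)
}
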