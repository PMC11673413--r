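# Preprocessing: background-noise subtraction, breast masking, and
# short-side rescaling, applied in that fixed order. The background estimate
# is the mean of the top-left N x M pixel block (N = M = 4), taken literally
# from the image corner with no fallback search.

#' Estimate the constant background intensity
#'
#' Arithmetic mean of the top-left `N x M` pixel block (rows `1..N`,
#' columns `1..M`).
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param N,M block size in rows and columns; both default to 4.
#' @return A list with `value` (the estimate), `N`, `M`, of class
#'   `bc_background`.
#' @export
estimate_background <- function(image, N = 4L, M = 4L) {
  if (nrow(image) < N || ncol(image) < M)
    stop("image (", nrow(image), "x", ncol(image),
         ") is smaller than the background block (", N, "x", M, ")")
  if (any(!is.finite(image))) stop("image intensities must be finite")
  structure(list(value = mean(image[seq_len(N), seq_len(M)]),
                 N = as.integer(N), M = as.integer(M)),
            class = "bc_background")
}

#' Subtract the background estimate from every pixel
#'
#' Each pixel becomes `max(0, pixel - bg$value)`; intensities are physical
#' magnitudes, so negative results are clamped to zero.
#'
#' @param image numeric matrix.
#' @param bg a [estimate_background()] result, or a single number.
#' @return A matrix of the same shape with non-negative entries.
#' @export
subtract_background <- function(image, bg = estimate_background(image)) {
  v <- if (is.list(bg)) bg$value else bg
  pmax(image - v, 0)
}

# round-half-away-from-zero, for deterministic scaled dimensions
round_half_up <- function(x) floor(x + 0.5)

#' Rescale so the shorter image side matches a target
#'
#' The scale factor is `target / min(height, width)`; both dimensions are
#' multiplied by it and rounded half-away-from-zero, preserving aspect ratio
#' within one pixel. Intensities are resampled bilinearly.
#'
#' @param image numeric matrix.
#' @param target length of the shorter output side, default 512.
#' @return A list with `image` (the rescaled matrix) and `scale`; multiply
#'   box coordinates by `scale` to map them onto the rescaled raster.
#' @export
rescale_to_short_side <- function(image, target = 512L) {
  h <- nrow(image); w <- ncol(image)
  if (h < 1 || w < 1) stop("degenerate image: ", h, "x", w)
  stopifnot(target >= 1)
  s <- target / min(h, w)
  nh <- as.integer(round_half_up(h * s)); nw <- as.integer(round_half_up(w * s))
  out <- if (nh == h && nw == w) image else
    as.matrix(EBImage::resize(EBImage::Image(image), w = nh, h = nw,
                              filter = "bilinear"))
  list(image = out, scale = s)
}

#' Apply a breast mask
#'
#' Pixels outside the mask are zeroed; pixels inside pass through unchanged.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape (nonzero = inside).
#' @return The masked image.
#' @export
apply_breast_mask <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(dim(image), collapse = "x"))
  image * (mask != 0)
}

#' Baseline breast segmentation mask
#'
#' A deterministic stand-in segmenter for background-subtracted slices: Otsu
#' threshold, largest connected foreground component, then morphological
#' closing. Any learned segmentation model can be plugged in wherever a mask
#' is accepted.
#'
#' @param image background-subtracted numeric matrix.
#' @param brush_size diameter of the disc brush used for closing.
#' @return A binary matrix (0/1) with a single foreground component, or all
#'   zeros (with a warning) when no foreground is found.
#' @export
baseline_breast_mask <- function(image, brush_size = 5L) {
  mx <- max(image)
  if (mx <= 0) {
    warning("empty foreground: returning an all-zero mask")
    return(matrix(0, nrow(image), ncol(image)))
  }
  norm <- EBImage::Image(image / mx)
  thr <- EBImage::otsu(norm)
  bw <- norm > thr
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(as.integer(lab))
  if (!length(tab) || max(tab) == 0) {
    warning("empty foreground: returning an all-zero mask")
    return(matrix(0, nrow(image), ncol(image)))
  }
  keep <- which.max(tab)
  comp <- EBImage::Image(as.numeric(lab == keep), dim = dim(image))
  closed <- EBImage::closing(comp, EBImage::makeBrush(brush_size, shape = "disc"))
  # closing of a connected set stays connected; re-binarize defensively
  out <- matrix(as.numeric(as.matrix(closed) > 0), nrow(image), ncol(image))
  out
}

#' Preprocess one slice
#'
#' Fixed order: background subtraction, breast masking, short-side rescaling.
#'
#' @param image numeric matrix.
#' @param target shorter-side target in pixels.
#' @param mask `TRUE` for the baseline segmenter, `FALSE`/`NULL` for none, or
#'   a binary matrix / function(image) supplying the mask.
#' @return A list with `image`, `scale`, `bg_value`.
#' @export
preprocess_image <- function(image, target = 512L, mask = TRUE) {
  bg <- estimate_background(image)
  img <- subtract_background(image, bg)
  if (isTRUE(mask)) mask <- baseline_breast_mask(img)
  if (is.function(mask)) mask <- mask(img)
  if (is.matrix(mask)) img <- apply_breast_mask(img, mask)
  sc <- rescale_to_short_side(img, target)
  list(image = sc$image, scale = sc$scale, bg_value = bg$value)
}

#' Preprocess a VOC dataset directory
#'
#' Applies [preprocess_image()] to every annotated image, scales the
#' annotation boxes accordingly, and writes a parallel VOC layout plus a
#' per-image scale table.
#'
#' @param in_dir,out_dir dataset roots (VOC2007 layout).
#' @param target shorter-side target in pixels.
#' @param mask as in [preprocess_image()].
#' @return A tibble (`image_id`, `scale`, `bg_value`), also written to
#'   `out_dir/preprocess_scales.csv`.
#' @export
preprocess_dataset <- function(in_dir, out_dir, target = 512L, mask = TRUE) {
  ds <- voc_dataset(in_dir)
  dir.create(file.path(out_dir, "JPEGImages"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "Annotations"), recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(ds)), function(i) {
    img <- read_image(ds$image_path[i])
    rec <- read_voc_annotation(ds$annotation_path[i])
    pp <- preprocess_image(img, target = target, mask = mask)
    rec$image_size <- c(ncol(pp$image), nrow(pp$image))
    if (nrow(rec$annotations)) {
      rec$annotations[BOX_COLS] <- rec$annotations[BOX_COLS] * pp$scale
      rec$annotations <- clip_boxes(rec$annotations, rec$image_size[1], rec$image_size[2])
    }
    write_image(pp$image, file.path(out_dir, "JPEGImages", paste0(ds$image_id[i], ".png")))
    write_voc_annotation(rec, file.path(out_dir, "Annotations", paste0(ds$image_id[i], ".xml")))
    tibble::tibble(image_id = ds$image_id[i], scale = pp$scale, bg_value = pp$bg_value)
  })
  sets <- file.path(in_dir, "ImageSets", "Main")
  if (dir.exists(sets)) {
    dir.create(file.path(out_dir, "ImageSets", "Main"), recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(sets, full.names = TRUE), file.path(out_dir, "ImageSets", "Main"))
  }
  write.csv(rows, file.path(out_dir, "preprocess_scales.csv"), row.names = FALSE)
  rows
}
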