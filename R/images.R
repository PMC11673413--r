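# Grayscale raster I/O. Images travel as plain numeric matrices [rows = y,
# cols = x] on a nominal 0-255 intensity scale; PNG files store intensity/255
# and TIFF files are read on the same scale.

#' Read a grayscale image
#'
#' Reads PNG (via \pkg{png}) or TIFF rasters into a numeric matrix on the
#' nominal 0-255 intensity scale; multi-channel rasters are averaged.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return A numeric matrix (rows = y, columns = x).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF rasters")
      tiff::readTIFF(path)
    },
    stop("unsupported image extension: ", ext))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  px * 255
}

#' Write a grayscale image as PNG
#'
#' Intensities are clamped to \[0, 255\] and stored as `intensity / 255`.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- pmin(pmax(image, 0), 255) / 255
  png::writePNG(m, path)
  invisible(path)
}
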