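# Breast geometry for four-quadrant localization. All x values are axial
# image coordinates; Y_mid is in anatomical units (y increasing toward the
# head). Sagittal image rows are converted to anatomical y via
# y_anat = sag_height - row when y_orientation = -1 (superior pixels have
# smaller row indices), or used as-is when y_orientation = +1.

#' Breast geometry for quadrant localization
#'
#' @param Y_mid anatomical y of the sagittal breast midline.
#' @param x_Rmid,x_Lmid axial x midlines of the low-x and high-x breast;
#'   must satisfy `x_Rmid < x_mid < x_Lmid`.
#' @param x_mid axial x midline between the two breasts.
#' @param axial_baseline axial y (row) of the chest-wall baseline.
#' @param sag_height sagittal image height in pixels, used for the row-to-
#'   anatomical-y flip.
#' @param y_orientation `-1` when superior is the smaller row index (the
#'   generator's convention), `+1` when rows already increase superiorly.
#' @return An object of class `bc_geometry`.
#' @export
bc_geometry <- function(Y_mid, x_Rmid, x_Lmid, x_mid = (x_Rmid + x_Lmid) / 2,
                        axial_baseline = 0, sag_height = NULL,
                        y_orientation = -1) {
  if (!(x_Rmid < x_mid && x_mid < x_Lmid))
    stop("geometry must satisfy x_Rmid < x_mid < x_Lmid")
  if (!y_orientation %in% c(-1, 1)) stop("y_orientation must be -1 or +1")
  if (y_orientation == -1 && is.null(sag_height))
    stop("sag_height is required when y_orientation is -1")
  structure(list(Y_mid = Y_mid, x_Rmid = x_Rmid, x_Lmid = x_Lmid,
                 x_mid = x_mid, axial_baseline = axial_baseline,
                 sag_height = sag_height, y_orientation = y_orientation),
            class = "bc_geometry")
}

# sagittal image row -> anatomical y
sag_to_anatomical <- function(y_img, g) {
  if (g$y_orientation == -1) g$sag_height - y_img else y_img
}

#' @export
print.bc_geometry <- function(x, ...) {
  cat(sprintf("<bc_geometry> Y_mid=%.1f x_Rmid=%.1f x_mid=%.1f x_Lmid=%.1f baseline=%.1f\n",
              x$Y_mid, x$x_Rmid, x$x_mid, x$x_Lmid, x$axial_baseline))
  invisible(x)
}

geometry_to_row <- function(g, case = NA_integer_) {
  tibble::tibble(case = case, Y_mid = g$Y_mid, x_Rmid = g$x_Rmid,
                 x_Lmid = g$x_Lmid, x_mid = g$x_mid,
                 axial_baseline = g$axial_baseline,
                 sag_height = g$sag_height, y_orientation = g$y_orientation)
}

row_to_geometry <- function(row) {
  bc_geometry(Y_mid = row$Y_mid, x_Rmid = row$x_Rmid, x_Lmid = row$x_Lmid,
              x_mid = row$x_mid, axial_baseline = row$axial_baseline,
              sag_height = row$sag_height, y_orientation = row$y_orientation)
}
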