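# Dual-plane four-quadrant 3D localization. The sagittal center gives the
# superior/inferior half ("up" when the anatomical y exceeds the breast
# midline Y_mid); the axial center gives medial/lateral ("outside" when x
# falls lateral to the breast midlines x_Rmid / x_Lmid). Boundary ties go
# to "down" and "inside" so the four indicators partition the plane.

QUADRANTS <- c("outside_up", "outside_down", "inside_up", "inside_down")

#' Four-quadrant localization of a lesion
#'
#' @param sag_center sagittal-plane center: `c(x, y)` in image coordinates
#'   (rows convert to anatomical y via the geometry), or a tibble with
#'   `x`, `y` columns.
#' @param ax_center axial-plane center, same forms.
#' @param geometry a [bc_geometry()].
#' @return Character vector of quadrant labels (one per row/center pair).
#' @export
locate_quadrant <- function(sag_center, ax_center, geometry) {
  sc <- center_xy(sag_center); ac <- center_xy(ax_center)
  y_anat <- sag_to_anatomical(sc$y, geometry)
  up <- y_anat > geometry$Y_mid
  outside <- ac$x < geometry$x_Rmid | ac$x > geometry$x_Lmid
  paste0(ifelse(outside, "outside", "inside"), ifelse(up, "_up", "_down"))
}

center_xy <- function(p) {
  if (is.data.frame(p)) list(x = p$x, y = p$y)
  else if (is.numeric(p) && length(p) == 2) list(x = p[1], y = p[2])
  else if (is.numeric(p) && is.matrix(p)) list(x = p[, 1], y = p[, 2])
  else stop("cannot interpret center coordinates")
}

#' Breast laterality from the axial center
#'
#' The printed rule: the lesion is in the left breast when the axial x lies
#' below the inter-breast midline `x_mid`, otherwise the right (ties go
#' right). Because displays may mirror patient left/right, `flip = TRUE`
#' reverses the labels.
#'
#' @param x_ax axial x coordinate(s) of the lesion center.
#' @param geometry a [bc_geometry()].
#' @param flip reverse the labels for mirrored display conventions.
#' @return Character vector: `"left"` or `"right"`.
#' @export
laterality <- function(x_ax, geometry, flip = FALSE) {
  out <- ifelse(x_ax < geometry$x_mid, "left", "right")
  if (flip) out <- ifelse(out == "left", "right", "left")
  out
}

#' Build a lesion case report
#'
#' Combines dual-plane fusion, quadrant localization, and laterality into
#' one flat record. With a single detected plane the report carries that
#' plane's diagnosis; the quadrant needs both planes and is `NA` otherwise.
#'
#' @param lesion_id lesion identifier.
#' @param axial_det,sagittal_det one-row detection tibbles for this lesion
#'   (box columns, `label`, `score`, `malignant_score`), or `NULL` when the
#'   lesion was not detected in that plane.
#' @param geometry a [bc_geometry()].
#' @param malignant_threshold retention threshold used for the per-plane
#'   malignancy calls.
#' @return A one-row tibble: `lesion_id`, `detected`, `diagnosis`,
#'   `laterality`, `quadrant`, per-plane centers and scores.
#' @export
build_case_report <- function(lesion_id, axial_det = NULL,
                              sagittal_det = NULL, geometry,
                              malignant_threshold = 0.5) {
  has_ax <- !is.null(axial_det) && nrow(axial_det) > 0
  has_sag <- !is.null(sagittal_det) && nrow(sagittal_det) > 0
  plane_malignant <- function(d, has)
    if (!has) NA else d$label == "malignant" && d$malignant_score > malignant_threshold
  diagnosis <- fuse_dual_plane(plane_malignant(axial_det, has_ax),
                               plane_malignant(sagittal_det, has_sag))
  ax_c <- if (has_ax) box_center(axial_det) else tibble::tibble(x = NA_real_, y = NA_real_)
  sag_c <- if (has_sag) box_center(sagittal_det) else tibble::tibble(x = NA_real_, y = NA_real_)
  tibble::tibble(
    lesion_id = lesion_id,
    detected = has_ax || has_sag,
    diagnosis = diagnosis,
    laterality = if (has_ax) laterality(ax_c$x, geometry) else NA_character_,
    quadrant = if (has_ax && has_sag)
      locate_quadrant(c(sag_c$x, sag_c$y), c(ax_c$x, ax_c$y), geometry)
      else NA_character_,
    axial_x = ax_c$x, axial_y = ax_c$y,
    sagittal_x = sag_c$x, sagittal_y = sag_c$y,
    axial_score = if (has_ax) axial_det$malignant_score else NA_real_,
    sagittal_score = if (has_sag) sagittal_det$malignant_score else NA_real_)
}
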