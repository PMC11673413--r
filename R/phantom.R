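# Deterministic dual-plane breast phantom. Each case renders the same lesion
# set in an axial slice (two half-ellipse breasts hanging from a chest-wall
# baseline) and a sagittal slice (one half-ellipse breast on a chest-wall
# edge), on a dark noisy background with a constant additive offset. Benign
# lesions are smooth rotated ellipses; malignant lesions are radially
# spiculated stars. The anterior-posterior depth of a lesion ties its axial
# row to its sagittal column, so both planes agree on one 3D position and
# one ground-truth quadrant.

#' Phantom generator settings
#'
#' Defaults define the package's reference study conditions: 128 x 128
#' slices, one lesion per case, a 50/50 benign/malignant mix, background
#' offset 40 with noise SD 8 on the nominal 0-255 scale, and strongly
#' spiculated malignant lesions (amplitude 0.5 of the base radius, 7 lobes).
#'
#' @param seed integer; per-case streams are derived as `xor(seed, case)`.
#' @param image_size integer `c(width, height)` of both planes.
#' @param n_cases number of cases in a generated dataset.
#' @param lesions_per_case integer range `c(min, max)` of lesions per case;
#'   all lesions of a case share one breast.
#' @param malignant_fraction probability a lesion is malignant.
#' @param background_offset constant additive background intensity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param benign_radius_range,malignant_radius_range base lesion radius range
#'   in pixels.
#' @param spiculation_amplitude malignant radius modulation as a fraction of
#'   the base radius, in `[0, 1)`.
#' @param spiculation_lobes number of spicule lobes.
#' @param breast_level,lesion_level rendered tissue intensities.
#' @param split named fractions for `train`/`val`/`test`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, image_size = c(128L, 128L), n_cases = 20L,
                         lesions_per_case = c(1L, 1L), malignant_fraction = 0.5,
                         background_offset = 40, noise_sd = 8,
                         benign_radius_range = c(6, 11),
                         malignant_radius_range = c(6, 11),
                         spiculation_amplitude = 0.5, spiculation_lobes = 7L,
                         breast_level = 110, lesion_level = 230,
                         split = c(train = 0.7, val = 0.15, test = 0.15)) {
  spec <- structure(list(seed = as.integer(seed),
                         image_size = as.integer(image_size),
                         n_cases = as.integer(n_cases),
                         lesions_per_case = as.integer(lesions_per_case),
                         malignant_fraction = malignant_fraction,
                         background_offset = background_offset,
                         noise_sd = noise_sd,
                         benign_radius_range = benign_radius_range,
                         malignant_radius_range = malignant_radius_range,
                         spiculation_amplitude = spiculation_amplitude,
                         spiculation_lobes = as.integer(spiculation_lobes),
                         breast_level = breast_level,
                         lesion_level = lesion_level,
                         split = split),
                    class = "phantom_spec")
  stopifnot(spec$malignant_fraction >= 0, spec$malignant_fraction <= 1,
            all(spec$benign_radius_range > 0),
            all(spec$malignant_radius_range > 0),
            spec$spiculation_amplitude >= 0, spec$spiculation_amplitude < 1,
            all(spec$image_size >= 32L),
            spec$lesions_per_case[1] >= 1L,
            abs(sum(spec$split) - 1) < 1e-8)
  spec
}

# pixel-center coordinate grids in continuous 0-based coordinates
pixel_grid <- function(H, W) {
  list(X = matrix(rep(seq_len(W) - 0.5, each = H), H, W),
       Y = matrix(rep(seq_len(H) - 0.5, W), H, W))
}

# mask of a rotated ellipse centered at (cx, cy)
ellipse_mask <- function(H, W, cx, cy, a, b, phi) {
  g <- pixel_grid(H, W)
  dx <- g$X - cx; dy <- g$Y - cy
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# mask of a spiculated star: radius r0 * (1 + A * sin(lobes * theta + phase))
star_mask <- function(H, W, cx, cy, r0, A, lobes, phase) {
  g <- pixel_grid(H, W)
  dx <- g$X - cx; dy <- g$Y - cy
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rho <= r0 * (1 + A * sin(lobes * theta + phase))
}

mask_bbox <- function(mask) {
  rows <- which(apply(mask, 1, any)); cols <- which(apply(mask, 2, any))
  c(x_min = min(cols) - 1, y_min = min(rows) - 1,
    x_max = max(cols), y_max = max(rows))
}

#' Generate one phantom case
#'
#' Deterministic given `(spec$seed, case_index)`. Returns both planes, their
#' annotations (shared `lesion_id`s), the case geometry, per-lesion ground
#' truth, the true breast masks, and the rendered lesion masks.
#'
#' @param spec a [phantom_spec()].
#' @param case_index positive integer case counter.
#' @return An object of class `phantom_case`.
#' @export
generate_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"), case_index >= 1)
  set.seed(bitwXor(spec$seed, as.integer(case_index)))
  W <- spec$image_size[1]; H <- spec$image_size[2]

  # axial anatomy: chest wall baseline on top, two breasts hanging down
  y0 <- 0.09 * H
  jit <- function(x, f = 0.03) x * runif(1, 1 - f, 1 + f)
  cx_R <- jit(0.26 * W); cx_L <- jit(0.74 * W)
  a_ax <- jit(0.22 * W); b_ax <- jit(0.55 * H)
  # sagittal anatomy: chest wall on the left edge, breast bulging right
  x0s <- 0.08 * W; cy_s <- jit(0.5 * H)
  a_sag <- jit(0.60 * W); b_sag <- jit(0.36 * H)

  gx <- pixel_grid(H, W)
  # a thin chest-wall band joins the breasts to one connected foreground,
  # kept clear of the 4 x 4 corner block used for background estimation
  band_ax <- max(y0 - 0.05 * H, 4.5)
  ax_breast <- ((((gx$X - cx_R) / a_ax)^2 + ((gx$Y - y0) / b_ax)^2 <= 1 |
                 ((gx$X - cx_L) / a_ax)^2 + ((gx$Y - y0) / b_ax)^2 <= 1) &
                gx$Y >= y0) |
               (gx$Y >= band_ax & gx$Y < y0 &
                gx$X >= cx_R - a_ax & gx$X <= cx_L + a_ax)
  band_sag <- max(x0s - 0.05 * W, 4.5)
  sag_breast <- ((((gx$X - x0s) / a_sag)^2 + ((gx$Y - cy_s) / b_sag)^2 <= 1) &
                 gx$X >= x0s) |
                (gx$X >= band_sag & gx$X < x0s &
                 gx$Y >= cy_s - b_sag & gx$Y <= cy_s + b_sag)

  geometry <- bc_geometry(Y_mid = H - cy_s, x_Rmid = cx_R, x_Lmid = cx_L,
                          x_mid = (cx_R + cx_L) / 2, axial_baseline = y0,
                          sag_height = H, y_orientation = -1)

  n_lesions <- if (spec$lesions_per_case[1] == spec$lesions_per_case[length(spec$lesions_per_case)])
    spec$lesions_per_case[1] else
    sample(spec$lesions_per_case[1]:spec$lesions_per_case[2], 1)
  side <- sample(c("low_x", "high_x"), 1)
  cx_b <- if (side == "low_x") cx_R else cx_L
  margin <- 6 # keeps box centers clear of every quadrant boundary

  placed <- list()
  lesions <- NULL
  for (k in seq_len(n_lesions)) {
    malignant <- runif(1) < spec$malignant_fraction
    rng <- if (malignant) spec$malignant_radius_range else spec$benign_radius_range
    ok <- FALSE
    for (try in seq_len(100L)) {
      r <- runif(1, rng[1], rng[2])
      re <- r * (1 + if (malignant) spec$spiculation_amplitude else 0.15)
      u_max <- a_ax - re - 3
      if (u_max <= margin) next
      u <- sample(c(-1, 1), 1) * runif(1, margin, u_max)
      v_max <- b_sag - re - 3
      if (v_max <= margin) next
      v <- sample(c(-1, 1), 1) * runif(1, margin, v_max)
      # corner condition: the (re + 3)-padded box around the lesion center
      # must stay inside both breast ellipses
      d_cap <- min(b_ax * sqrt(1 - ((abs(u) + re + 3) / a_ax)^2),
                   a_sag * sqrt(1 - ((abs(v) + re + 3) / b_sag)^2)) - re - 3
      if (d_cap <= re + 3) next
      d <- runif(1, re + 3, d_cap)
      clash <- FALSE
      for (p in placed) {
        if (abs(u - p$u) < re + p$re + 4 && abs(d - p$d) < re + p$re + 4) clash <- TRUE
        if (abs(v - p$v) < re + p$re + 4 && abs(d - p$d) < re + p$re + 4) clash <- TRUE
      }
      if (clash) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place lesion ", k, " inside the breast for case ", case_index)
    placed[[k]] <- list(u = u, v = v, d = d, re = re)
    lesions <- dplyr::bind_rows(lesions, tibble::tibble(
      lesion_id = sprintf("case%04d_les%d", case_index, k),
      label = if (malignant) "malignant" else "benign",
      r = r, u = u, v = v, d = d,
      ax_x = cx_b + u, ax_y = y0 + d,
      sag_x = x0s + d, sag_y = cy_s + v))
  }

  render_plane <- function(breast, centers_x, centers_y, radii) {
    img <- matrix(0, H, W)
    img[breast] <- spec$breast_level
    masks <- vector("list", nrow(lesions))
    ann <- NULL
    for (k in seq_len(nrow(lesions))) {
      r_k <- radii[k]
      if (lesions$label[k] == "malignant") {
        m <- star_mask(H, W, centers_x[k], centers_y[k], r_k,
                       spec$spiculation_amplitude, spec$spiculation_lobes,
                       runif(1, 0, 2 * pi))
      } else {
        ar <- runif(1, 0.85, 1.15)
        m <- ellipse_mask(H, W, centers_x[k], centers_y[k],
                          r_k * ar, r_k / ar, runif(1, 0, pi))
      }
      img[m] <- spec$lesion_level
      masks[[k]] <- m
      bb <- mask_bbox(m)
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        x_min = bb[["x_min"]], y_min = bb[["y_min"]],
        x_max = bb[["x_max"]], y_max = bb[["y_max"]],
        label = lesions$label[k], lesion_id = lesions$lesion_id[k]))
    }
    img <- img + spec$background_offset +
      matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    list(image = pmin(pmax(img, 0), 255), annotations = ann,
         lesion_masks = setNames(masks, lesions$lesion_id))
  }

  ax <- render_plane(ax_breast, lesions$ax_x, lesions$ax_y, lesions$r)
  sag_radii <- lesions$r * runif(nrow(lesions), 0.8, 1.2)
  sg <- render_plane(sag_breast, lesions$sag_x, lesions$sag_y, sag_radii)
  ax$annotations$plane <- "axial"; sg$annotations$plane <- "sagittal"

  truth <- dplyr::mutate(
    lesions,
    quadrant = paste0(ifelse(.data$u < 0 & side == "low_x" | .data$u > 0 & side == "high_x",
                             "outside", "inside"),
                      ifelse(.data$v < 0, "_up", "_down")),
    laterality = ifelse(.data$ax_x < geometry$x_mid, "left", "right"))

  structure(list(case_index = as.integer(case_index),
                 axial_image = ax$image, sagittal_image = sg$image,
                 axial_annotations = ax$annotations,
                 sagittal_annotations = sg$annotations,
                 geometry = geometry,
                 lesions = truth,
                 axial_breast_mask = ax_breast * 1,
                 sagittal_breast_mask = sag_breast * 1,
                 axial_lesion_masks = ax$lesion_masks,
                 sagittal_lesion_masks = sg$lesion_masks),
            class = "phantom_case")
}

#' Generate a phantom dataset in VOC2007 layout
#'
#' Writes `JPEGImages/`, `Annotations/`, `ImageSets/Main/{train,val,test}.txt`,
#' a per-case `geometry.csv`, and `manifest.csv` under `out_dir`. Image ids
#' are `case%04d_ax` / `case%04d_sag`; both planes of a case share a split.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return The manifest tibble (`case`, `split`, `plane`, `image_id`,
#'   `lesion_id`, `label`, `quadrant`, `laterality`), invisibly.
#' @export
generate_dataset <- function(spec, out_dir) {
  for (d in c("JPEGImages", "Annotations", file.path("ImageSets", "Main")))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  n <- spec$n_cases
  n_train <- round(spec$split[["train"]] * n)
  n_val <- round(spec$split[["val"]] * n)
  splits <- rep(c("train", "val", "test"),
                c(n_train, n_val, n - n_train - n_val))
  manifest <- NULL
  geo <- NULL
  ids <- list(train = character(), val = character(), test = character())
  for (i in seq_len(n)) {
    cs <- generate_case(spec, i)
    for (plane in c("axial", "sagittal")) {
      img <- if (plane == "axial") cs$axial_image else cs$sagittal_image
      ann <- if (plane == "axial") cs$axial_annotations else cs$sagittal_annotations
      id <- sprintf("case%04d_%s", i, if (plane == "axial") "ax" else "sag")
      write_image(img, file.path(out_dir, "JPEGImages", paste0(id, ".png")))
      rec <- voc_record(paste0(id, ".png"), c(ncol(img), nrow(img)),
                        ann, plane = plane)
      write_voc_annotation(rec, file.path(out_dir, "Annotations", paste0(id, ".xml")))
      ids[[splits[i]]] <- c(ids[[splits[i]]], id)
      manifest <- dplyr::bind_rows(manifest, tibble::tibble(
        case = i, split = splits[i], plane = plane, image_id = id,
        lesion_id = cs$lesions$lesion_id, label = cs$lesions$label,
        quadrant = cs$lesions$quadrant, laterality = cs$lesions$laterality))
    }
    geo <- dplyr::bind_rows(geo, geometry_to_row(cs$geometry, case = i))
  }
  for (s in names(ids))
    writeLines(ids[[s]], file.path(out_dir, "ImageSets", "Main", paste0(s, ".txt")))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(geo, file.path(out_dir, "geometry.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Isoperimetric boundary roughness of a lesion mask
#'
#' `perimeter^2 / (4 * pi * area)`: at least 1, with equality only for a
#' disk. The perimeter is measured on the half-level contour of a lightly
#' smoothed mask (Gaussian blur, then marching squares via
#' [grDevices::contourLines()]); the smoothing suppresses the staircase
#' inflation a raw rasterized boundary would add.
#'
#' @param mask binary matrix.
#' @param sigma Gaussian smoothing radius in pixels before contouring.
#' @return A single number `>= 1` up to discretization error.
#' @examples
#' g <- expand.grid(x = 1:64, y = 1:64)
#' disk <- matrix((g$x - 32)^2 + (g$y - 32)^2 <= 20^2, 64, 64)
#' boundary_roughness(disk) # close to 1
#' @export
boundary_roughness <- function(mask, sigma = 0.9) {
  m <- (mask != 0) * 1
  if (!any(m == 1)) stop("empty mask")
  area <- sum(m)
  padded <- matrix(0, nrow(m) + 6, ncol(m) + 6)
  padded[4:(nrow(m) + 3), 4:(ncol(m) + 3)] <- m
  padded <- as.matrix(EBImage::gblur(EBImage::Image(padded), sigma = sigma))
  cl <- grDevices::contourLines(x = seq_len(nrow(padded)),
                                y = seq_len(ncol(padded)),
                                z = padded, levels = 0.5)
  per <- sum(vapply(cl, function(cc) {
    x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
  per^2 / (4 * pi * area)
}
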