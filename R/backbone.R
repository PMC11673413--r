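# Backbone and feature pyramid. Two presets share one layout mechanism:
# `vgg16` is the 13-convolution configuration (64-64 / 128-128 / 256x3 /
# 512x3 / 512x3) and `tiny` a 4-block desk-scale backbone (one 3x3
# convolution per block, 8-16-16-16 channels) with an optional fifth block
# feeding the pyramid. Each stage ends in 2x2 max pooling, so stage outputs
# sit at strides 2, 4, 8, 16, 32; the stride-16 stage is the single-level
# terminal map, and stages 2-5 are the pyramid inputs C2-C5.

backbone_layout <- function(preset) {
  switch(preset,
    vgg16 = list(stages = list(c(64, 64), c(128, 128), c(256, 256, 256),
                               c(512, 512, 512), c(512, 512, 512)),
                 fpn_channels = 256L),
    tiny = list(stages = list(8, 16, 16, 16, 16), fpn_channels = 16L),
    stop("unknown backbone preset: ", preset))
}

init_backbone_params <- function(preset, use_fpn, in_channels = 1L) {
  layout <- backbone_layout(preset)
  n_stages <- if (use_fpn) 5L else 4L
  params <- list()
  cin <- in_channels
  for (s in seq_len(n_stages)) {
    for (i in seq_along(layout$stages[[s]])) {
      cout <- layout$stages[[s]][i]
      params[[sprintf("bb.s%d.c%d.w", s, i)]] <- he_conv(3, 3, cin, cout)
      params[[sprintf("bb.s%d.c%d.b", s, i)]] <- numeric(cout)
      cin <- cout
    }
  }
  if (use_fpn) {
    fc <- layout$fpn_channels
    chans <- vapply(layout$stages, function(v) v[length(v)], 1)[2:5]
    for (k in 2:5) {
      params[[sprintf("fpn.lat%d.w", k)]] <- he_conv(1, 1, chans[k - 1], fc)
      params[[sprintf("fpn.lat%d.b", k)]] <- numeric(fc)
      params[[sprintf("fpn.sm%d.w", k)]] <- he_conv(3, 3, fc, fc)
      params[[sprintf("fpn.sm%d.b", k)]] <- numeric(fc)
    }
  }
  params
}

#' Backbone forward pass
#'
#' Runs the convolutional backbone on a preprocessed slice. Intensities on
#' the nominal 0-255 scale are divided by 255 on entry.
#'
#' @param model a `bc_rcnn_model` (see [bc_model()]).
#' @param image numeric matrix (one slice).
#' @return A list with `stages` (stage outputs `S1..S4/S5` at strides
#'   2, 4, 8, 16, 32), `terminal` (the stride-16 map), and forward caches
#'   used by training.
#' @export
backbone_forward <- function(model, image) {
  if (min(dim(image)) < 16L)
    stop("image is smaller than one stride-16 cell")
  x <- array(image / 255, c(nrow(image), ncol(image), 1L))
  params <- model$params
  layout <- backbone_layout(model$config$backbone_preset)
  n_stages <- if (model$config$use_fpn) 5L else 4L
  caches <- list()
  stages <- list()
  for (s in seq_len(n_stages)) {
    for (i in seq_along(layout$stages[[s]])) {
      cv <- conv_fw(x, params[[sprintf("bb.s%d.c%d.w", s, i)]],
                    params[[sprintf("bb.s%d.c%d.b", s, i)]])
      rl <- relu_fw(cv$y)
      caches[[sprintf("s%d.c%d", s, i)]] <- list(conv = cv, relu = rl)
      x <- rl$y
    }
    mp <- maxpool2_fw(x)
    caches[[sprintf("s%d.pool", s)]] <- list(idx = mp$idx, xdim = dim(x))
    x <- mp$y
    stages[[sprintf("S%d", s)]] <- x
  }
  list(stages = stages, terminal = stages[["S4"]], caches = caches)
}

# g_stages: named list (S1..S5) of gradients on stage outputs; missing or
# NULL entries contribute nothing.
backbone_backward <- function(model, caches, g_stages, ge) {
  layout <- backbone_layout(model$config$backbone_preset)
  n_stages <- if (model$config$use_fpn) 5L else 4L
  g <- NULL
  for (s in rev(seq_len(n_stages))) {
    gs <- g_stages[[sprintf("S%d", s)]]
    if (!is.null(gs)) g <- if (is.null(g)) gs else g + gs
    if (is.null(g)) next
    pc <- caches[[sprintf("s%d.pool", s)]]
    g <- maxpool2_bw(g, pc$idx, pc$xdim)
    for (i in rev(seq_along(layout$stages[[s]]))) {
      cc <- caches[[sprintf("s%d.c%d", s, i)]]
      g <- relu_bw(cc$relu, g)
      # the input image needs no gradient, so the first convolution skips gx
      first <- s == 1L && i == 1L
      bw <- conv2d_bw(cc$conv$x, cc$conv$w, g, cc$conv$pad, first)
      grad_add(ge, sprintf("bb.s%d.c%d.w", s, i), bw$gw)
      grad_add(ge, sprintf("bb.s%d.c%d.b", s, i), bw$gb)
      g <- bw$gx
    }
  }
  invisible(NULL)
}

# nearest-neighbor 2x upsample cropped to a target spatial size
up_crop_fw <- function(x, target_hw) {
  y <- upsample2_fw(x)
  list(y = y[seq_len(target_hw[1]), seq_len(target_hw[2]), , drop = FALSE],
       full_dim = dim(y))
}

up_crop_bw <- function(cache, gy) {
  g <- array(0, cache$full_dim)
  g[seq_len(dim(gy)[1]), seq_len(dim(gy)[2]), ] <- gy
  upsample2_bw(g)
}

#' Feature pyramid forward pass
#'
#' Builds P2-P6 from backbone stages C2-C5: 1x1 lateral projections, 2x
#' nearest-neighbor top-down upsampling with elementwise sums, a 3x3
#' smoothing convolution per level, and P6 as a stride-2 subsample of P5.
#'
#' @param model a `bc_rcnn_model` with `use_fpn = TRUE`.
#' @param stages backbone stage outputs (`S2`..`S5` used as C2..C5).
#' @return A list with `levels` (named `P2`..`P6`, each `list(map, stride)`)
#'   and forward caches.
#' @export
fpn_forward <- function(model, stages) {
  params <- model$params
  caches <- list()
  lat <- list()
  for (k in 2:5) {
    cv <- conv_fw(stages[[sprintf("S%d", k)]],
                  params[[sprintf("fpn.lat%d.w", k)]],
                  params[[sprintf("fpn.lat%d.b", k)]])
    caches[[sprintf("lat%d", k)]] <- cv
    lat[[sprintf("L%d", k)]] <- cv$y
  }
  merged <- list(L5 = lat$L5)
  for (k in 4:2) {
    up <- up_crop_fw(merged[[sprintf("L%d", k + 1)]],
                     dim(lat[[sprintf("L%d", k)]])[1:2])
    caches[[sprintf("up%d", k)]] <- up
    merged[[sprintf("L%d", k)]] <- lat[[sprintf("L%d", k)]] + up$y
  }
  levels <- list()
  for (k in 2:5) {
    sm <- conv_fw(merged[[sprintf("L%d", k)]],
                  params[[sprintf("fpn.sm%d.w", k)]],
                  params[[sprintf("fpn.sm%d.b", k)]])
    caches[[sprintf("sm%d", k)]] <- sm
    levels[[sprintf("P%d", k)]] <- list(map = sm$y, stride = 2L^k)
  }
  p6 <- maxpool2_fw(levels$P5$map)
  caches$p6 <- list(idx = p6$idx, xdim = dim(levels$P5$map))
  levels$P6 <- list(map = p6$y, stride = 64L)
  list(levels = levels, caches = caches)
}

# g_levels: named list P2..P6 of gradient arrays (NULL entries allowed).
# Returns gradients with respect to stages S2..S5 and accumulates parameter
# gradients into `ge`.
fpn_backward <- function(model, caches, g_levels, ge) {
  zdim <- function(k) dim(caches[[sprintf("sm%d", k)]]$y)
  gP <- list()
  for (k in 2:5) {
    g <- g_levels[[sprintf("P%d", k)]]
    gP[[sprintf("P%d", k)]] <- if (is.null(g)) array(0, zdim(k)) else g
  }
  if (!is.null(g_levels$P6))
    gP$P5 <- gP$P5 + maxpool2_bw(g_levels$P6, caches$p6$idx, caches$p6$xdim)
  g_stages <- list()
  g_merged <- NULL
  for (k in 2:5) {
    bw <- conv_bw(caches[[sprintf("sm%d", k)]], gP[[sprintf("P%d", k)]])
    grad_add(ge, sprintf("fpn.sm%d.w", k), bw$gw)
    grad_add(ge, sprintf("fpn.sm%d.b", k), bw$gb)
    gP[[sprintf("P%d", k)]] <- bw$gx # now gradient of the merged map
  }
  # top-down sums: merged_k = lat_k + upcrop(merged_{k+1})
  for (k in 2:4)
    gP[[sprintf("P%d", k + 1)]] <- gP[[sprintf("P%d", k + 1)]] +
      up_crop_bw(caches[[sprintf("up%d", k)]], gP[[sprintf("P%d", k)]])
  for (k in 2:5) {
    bw <- conv_bw(caches[[sprintf("lat%d", k)]], gP[[sprintf("P%d", k)]])
    grad_add(ge, sprintf("fpn.lat%d.w", k), bw$gw)
    grad_add(ge, sprintf("fpn.lat%d.b", k), bw$gb)
    g_stages[[sprintf("S%d", k)]] <- bw$gx
  }
  g_stages
}
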