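# First-stage detector: anchors, pyramid level assignment, ROI align,
# backbone/FPN shape contracts, proposals, and the detection head.

test_that("anchor grids have the documented shape counts and geometry", {
  cfg <- bc_config()
  # classic single-level setting: 3 scales x 3 ratios
  a9 <- build_anchor_grid(c(4, 5), 16, cfg$anchor_scales, cfg$anchor_ratios)
  expect_equal(nrow(a9), 4 * 5 * 9)
  # pyramid level: two neighbor scales x 3 ratios
  a6 <- build_anchor_grid(c(4, 5), 16, fpn_level_scales(64), cfg$anchor_ratios)
  expect_equal(nrow(a6), 4 * 5 * 6)
  # scale 16, ratio 1 anchor at the first stride-16 cell
  a1 <- build_anchor_grid(c(1, 1), 16, 16, 1)
  expect_equal(unlist(a1, use.names = FALSE), c(0, 0, 16, 16))
  expect_equal(unlist(box_center(a1)), c(x = 8, y = 8))
  # area and aspect: w/h = ratio, w*h = scale^2
  ar <- build_anchor_grid(c(1, 1), 16, 32, c(0.5, 1, 2))
  w <- ar$x_max - ar$x_min; h <- ar$y_max - ar$y_min
  expect_equal(w * h, rep(32^2, 3))
  expect_equal(w / h, c(0.5, 1, 2))
  expect_error(build_anchor_grid(c(2, 2), 16, numeric(0)), "non-empty")
})

test_that("pyramid level assignment follows the canonical-size rule", {
  expect_equal(assign_fpn_level(c(0, 0, 160, 160)), 4L)
  expect_equal(assign_fpn_level(c(0, 0, 40, 40)), 2L)
  expect_equal(assign_fpn_level(c(0, 0, 1280, 1280)), 5L)
  expect_error(assign_fpn_level(c(0, 0, 0, 10)), "zero-area")
  # monotone non-decreasing in area
  sizes <- sort(runif(50, 4, 2000))
  lv <- assign_fpn_level(cbind(0, 0, sizes, sizes))
  expect_true(all(diff(lv) >= 0))
})

test_that("roi_align preserves constants and matches the analytic ramp", {
  const <- array(3.5, c(10, 10, 2))
  p <- roi_align(const, 1, c(1, 1, 8, 8), pooled_size = 7)
  expect_equal(dim(p), c(7, 7, 2, 1))
  expect_true(all(abs(p - 3.5) < 1e-12))
  # f(x, y) = x on the lattice: bins equal the mean sample x coordinate
  W <- 20
  ramp <- array(rep(seq_len(W) - 1, each = 16), c(16, W, 1))
  box <- c(4.3, 2.7, 15.1, 11.9)
  p <- roi_align(ramp, 1, box, pooled_size = 3)
  bw <- (box[3] - box[1]) / 3
  for (pj in 1:3) {
    xs <- box[1] - 0.5 + (pj - 1 + c(0.25, 0.75)) * bw
    expect_equal(unname(p[, pj, 1, 1]), rep(mean(xs), 3), tolerance = 1e-5)
  }
  expect_error(roi_align(const, 1, c(0, 0, 5, 0)), "positive area")
  expect_error(roi_align(const, 1, c(50, 50, 60, 60)), "outside")
})

test_that("roi_align equals the direct bilinear oracle on random instances", {
  set.seed(77)
  for (i in 1:120) {
    H <- sample(6:12, 1); W <- sample(6:12, 1); C <- sample(1:2, 1)
    f <- array(rnorm(H * W * C), c(H, W, C))
    stride <- sample(c(1, 2, 4), 1)
    b <- c(runif(1, 0, W * stride / 2), runif(1, 0, H * stride / 2), 0, 0)
    b[3] <- b[1] + runif(1, 1, W * stride / 2)
    b[4] <- b[2] + runif(1, 1, H * stride / 2)
    P <- sample(2:4, 1)
    got <- roi_align(f, stride, b, pooled_size = P)
    want <- oracle_roi_align(f, stride, b, P)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-10)
  }
})

test_that("backbone presets produce stride-16 terminal maps", {
  cfg <- tiny_test_config(use_fpn = FALSE)
  model <- bc_model(cfg)
  out <- backbone_forward(model, matrix(100, 512, 512))
  expect_equal(dim(out$terminal)[1:2], c(32, 32))
  expect_lt(sum(vapply(model$params[grep("^bb", names(model$params))],
                       length, 1)), 1e6)
  # constant-zero input gives a constant map at every spatial location
  z <- backbone_forward(model, matrix(0, 64, 64))$terminal
  expect_equal(max(apply(z, 3, function(s) diff(range(s)))), 0)
  expect_error(backbone_forward(model, matrix(0, 8, 8)), "stride")
  # the full backbone configuration: 13 convolutional layers, stage widths
  expect_length(unlist(backbone_layout("vgg16")$stages), 13)
  expect_equal(backbone_layout("vgg16")$stages[[5]], c(512, 512, 512))
})

test_that("feature pyramid levels have the contracted shapes and strides", {
  model <- bc_model(tiny_test_config())
  bb <- backbone_forward(model, matrix(50, 128, 128))
  fp <- fpn_forward(model, bb$stages)
  expect_named(fp$levels, paste0("P", 2:6))
  strides <- vapply(fp$levels, `[[`, 1, "stride")
  expect_equal(unname(strides), c(4, 8, 16, 32, 64))
  expect_equal(dim(fp$levels$P2$map)[1:2], dim(bb$stages$S2)[1:2])
  for (k in 2:5)
    expect_equal(dim(fp$levels[[paste0("P", k)]]$map)[1:2], c(128, 128) / 2^k)
  # all-zero stages propagate to an all-zero pyramid
  zs <- lapply(bb$stages, function(s) array(0, dim(s)))
  fpz <- fpn_forward(model, zs)
  expect_true(all(vapply(fpz$levels, function(l) max(abs(l$map)), 1) == 0))
})

test_that("an identity lateral path reproduces the smoothed stage map", {
  model <- bc_model(tiny_test_config())
  # identity 1x1 laterals, zero deeper stages: P2 = smooth(C2)
  for (k in 2:5) {
    w <- model$params[[sprintf("fpn.lat%d.w", k)]] * 0
    for (c in seq_len(dim(w)[3])) w[1, 1, c, c] <- 1
    model$params[[sprintf("fpn.lat%d.w", k)]] <- w
    model$params[[sprintf("fpn.lat%d.b", k)]][] <- 0
  }
  bb <- backbone_forward(model, matrix(80, 128, 128))
  stages <- bb$stages
  for (nm in c("S3", "S4", "S5")) stages[[nm]] <- array(0, dim(stages[[nm]]))
  fp <- fpn_forward(model, stages)
  direct <- conv_fw(stages$S2, model$params[["fpn.sm2.w"]],
                    model$params[["fpn.sm2.b"]])$y
  expect_equal(fp$levels$P2$map, direct, tolerance = 1e-12)
})

test_that("proposals have the fixed candidate count sorted by objectness", {
  set.seed(12)
  model <- bc_model(tiny_test_config(seed = 12))
  bb <- backbone_forward(model, matrix(runif(128 * 128, 0, 200), 128, 128))
  lv <- model_levels(model, bb)
  rpn_out <- rpn_forward(model, lv$rpn)
  props <- propose(rpn_out, c(128, 128), model$config)
  expect_equal(nrow(props), 300)
  expect_true(all(diff(props$objectness) <= 1e-12))
  m <- box_matrix(props)
  expect_true(all(m[, 1] >= 0 & m[, 3] <= 128 & m[, 2] >= 0 & m[, 4] <= 128))
  # anchor count bookkeeping: H*W*shapes per level
  for (nm in names(rpn_out)) {
    hw <- prod(dim(lv$rpn[[nm]]$map)[1:2])
    expect_equal(nrow(rpn_out[[nm]]$anchors), hw * 6)
    expect_length(rpn_out[[nm]]$objectness, hw * 6)
  }
})

test_that("detection head emits [n, 4K] deltas and normalized [n, K] scores", {
  model <- bc_model(tiny_test_config())
  pooled <- array(rnorm(7 * 7 * 16 * 300), c(7, 7, 16, 300))
  out <- detection_head(model, pooled)
  expect_equal(dim(out$roi_deltas), c(300, 12))
  expect_equal(dim(out$roi_scores), c(300, 3))
  expect_equal(rowSums(out$roi_scores), rep(1, 300), tolerance = 1e-5)
  # K = 2 configuration scales the head accordingly
  m2 <- bc_model(tiny_test_config(num_classes = 2))
  out2 <- detection_head(m2, pooled)
  expect_equal(dim(out2$roi_deltas), c(300, 8))
  expect_equal(dim(out2$roi_scores), c(300, 2))
})
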