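# Preprocessing: background estimation/subtraction, rescaling, masking.

test_that("background estimate is the mean of the top-left block", {
  expect_equal(estimate_background(matrix(0, 8, 8))$value, 0)
  m <- matrix(0, 8, 8)
  m[1:4, 1:4] <- matrix(1:16, 4, 4)
  expect_equal(estimate_background(m)$value, 8.5)
  bg <- estimate_background(matrix(rnorm(100), 10, 10))
  expect_equal(c(bg$N, bg$M), c(4L, 4L))
  expect_error(estimate_background(matrix(0, 3, 8)), "smaller")
})

test_that("background estimate equals a brute-force double loop", {
  set.seed(5)
  for (i in 1:50) {
    m <- matrix(abs(rnorm(15 * 12, 50, 20)), 15, 12)
    n <- sample(2:6, 1); k <- sample(2:6, 1)
    acc <- 0
    for (r in seq_len(n)) for (cc in seq_len(k)) acc <- acc + m[r, cc]
    expect_equal(estimate_background(m, n, k)$value, acc / (n * k))
  }
})

test_that("subtraction clamps at zero and cancels constants", {
  cimg <- matrix(7, 6, 6)
  expect_equal(subtract_background(cimg), matrix(0, 6, 6))
  expect_equal(subtract_background(matrix(c(10, 3), 1), 5), matrix(c(5, 0), 1))
  img <- matrix(abs(rnorm(64, 40, 10)), 8, 8)
  out <- subtract_background(img)
  expect_true(all(out >= 0))
  expect_equal(dim(out), dim(img))
  # after one subtraction the re-estimated background is near zero
  expect_lt(estimate_background(out)$value, estimate_background(img)$value)
})

test_that("short-side rescaling fixes the shorter dimension at the target", {
  id <- rescale_to_short_side(matrix(1, 512, 768), 512)
  expect_equal(id$scale, 1)
  expect_equal(dim(id$image), c(512, 768))
  up <- rescale_to_short_side(matrix(rnorm(256 * 512), 256, 512), 512)
  expect_equal(up$scale, 2)
  expect_equal(dim(up$image), c(512, 1024))
  expect_equal(formals(rescale_to_short_side)$target, 512L)
  set.seed(9)
  for (i in 1:20) {
    h <- sample(40:300, 1); w <- sample(40:300, 1); t <- sample(c(64, 128, 512), 1)
    sc <- rescale_to_short_side(matrix(0, h, w), t)
    expect_lte(abs(min(dim(sc$image)) - t), 1)
    # aspect ratio preserved up to the rounding of both dimensions
    expect_lte(abs(dim(sc$image)[1] / dim(sc$image)[2] - h / w) *
                 max(dim(sc$image)), 2)
    expect_equal(dim(sc$image),
                 as.integer(floor(c(h, w) * sc$scale + 0.5)))
    # mapping boxes by scale and back is the identity
    b <- random_box(min(h, w))
    expect_equal((b * sc$scale) / sc$scale, b, tolerance = 1e-6)
  }
  expect_error(rescale_to_short_side(matrix(numeric(), 0, 0), 512), "degenerate")
})

test_that("mask application zeroes exactly the outside pixels", {
  img <- matrix(rnorm(48, 10), 6, 8)
  expect_equal(apply_breast_mask(img, matrix(1, 6, 8)), img)
  expect_equal(apply_breast_mask(img, matrix(0, 6, 8)), matrix(0, 6, 8))
  half <- matrix(0, 6, 8); half[, 1:4] <- 1
  out <- apply_breast_mask(img, half)
  expect_equal(sum(out[, 5:8] != 0), 0)
  expect_equal(out[, 1:4], img[, 1:4])
  expect_error(apply_breast_mask(img, matrix(1, 3, 3)), "shape")
})

test_that("baseline mask recovers the phantom breast region", {
  for (i in 1:4) {
    cs <- generate_case(phantom_spec(seed = 17), i)
    for (plane in c("axial", "sagittal")) {
      img <- if (plane == "axial") cs$axial_image else cs$sagittal_image
      truth <- if (plane == "axial") cs$axial_breast_mask else cs$sagittal_breast_mask
      m <- baseline_breast_mask(subtract_background(img))
      expect_true(all(m %in% c(0, 1)))
      # single connected component
      expect_equal(max(as.integer(EBImage::bwlabel(EBImage::Image(m)))), 1)
      coverage <- sum(m * truth) / sum(truth)
      iou_mask <- sum(m & truth) / sum(m | truth)
      expect_gte(coverage, 0.95)
      expect_gte(iou_mask, 0.8)
    }
  }
})

test_that("pure-noise images give an empty mask with a warning", {
  set.seed(2)
  expect_warning(m <- baseline_breast_mask(matrix(0, 32, 32)), "empty")
  expect_equal(sum(m), 0)
})

test_that("the full preprocessing chain runs in fixed order and reports scale", {
  cs <- generate_case(phantom_spec(seed = 23), 2)
  pp <- preprocess_image(cs$axial_image, target = 128)
  expect_equal(pp$scale, 1)
  expect_equal(pp$bg_value, mean(cs$axial_image[1:4, 1:4]))
  # masked background area is exactly zero after preprocessing
  expect_lt(mean(pp$image[1:4, 1:4]), 1e-9)
})
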