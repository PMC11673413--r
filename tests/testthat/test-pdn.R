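# Second stage: class-conditional refinement, size-bin level assignment,
# deep feature extraction, classification/retention, dual-plane fusion,
# and the composite loss.

test_that("refinement with zero deltas returns the proposals unchanged", {
  n <- 300
  props <- cbind(runif(n, 0, 50), runif(n, 0, 50),
                 runif(n, 60, 120), runif(n, 60, 120))
  for (cls in 0:2) {
    scores <- matrix(0.1, n, 3); scores[, cls + 1] <- 0.8
    head_out <- list(roi_scores = scores, roi_deltas = matrix(0, n, 12))
    ref <- refine_rois(head_out, props, c(128, 128))
    expect_identical(box_matrix(ref), props)
    expect_equal(ref$first_label, rep(cls, n))
  }
  expect_equal(nrow(ref), 300)
})

test_that("refinement uses the argmax class's delta slice", {
  prop <- c(10, 10, 50, 50)
  deltas <- matrix(0, 1, 12)
  deltas[1, 9:12] <- c(0.1, -0.1, log(1.5), log(0.5)) # malignant slice
  head_out <- list(roi_scores = matrix(c(0.1, 0.2, 0.7), 1),
                   roi_deltas = deltas)
  ref <- refine_rois(head_out, prop, c(128, 128))
  expect_equal(ref$first_label, 2L)
  want <- decode_deltas(prop, deltas[, 9:12, drop = FALSE],
                        width = 128, height = 128)
  expect_equal(box_matrix(ref), box_matrix(want))
  # background argmax keeps the proposal even with nonzero deltas
  head_bg <- list(roi_scores = matrix(c(0.8, 0.1, 0.1), 1),
                  roi_deltas = matrix(1, 1, 12))
  refb <- refine_rois(head_bg, prop, c(128, 128))
  expect_equal(unlist(box_matrix(refb)[1, ]), prop)
  expect_equal(refb$first_label, 0L)
})

test_that("argmax ties break toward the lower class index", {
  head_out <- list(roi_scores = matrix(c(0.4, 0.4, 0.2), 1),
                   roi_deltas = matrix(0, 1, 12))
  expect_equal(refine_rois(head_out, c(0, 0, 10, 10), c(64, 64))$first_label, 0L)
})

test_that("PDN size bins partition the positive sizes at 64 and 128", {
  expect_equal(assign_pdn_level(c(0, 0, 32, 32)), 2L)
  expect_equal(assign_pdn_level(c(0, 0, 100, 100)), 3L)
  expect_equal(assign_pdn_level(c(0, 0, 200, 128)), 4L) # sqrt(200*128) = 160
  # boundary sizes land in the closed middle bin
  expect_equal(assign_pdn_level(c(0, 0, 64, 64)), 3L)
  expect_equal(assign_pdn_level(c(0, 0, 128, 128)), 3L)
  expect_error(assign_pdn_level(c(0, 0, 0, 5)), "zero-area")
  # no gaps or overlaps over random sizes
  sizes <- runif(500, 0.5, 400)
  lv <- assign_pdn_level(cbind(0, 0, sizes, sizes))
  expect_true(all(lv %in% 2:4))
  expect_equal(lv, ifelse(sizes < 64, 2L, ifelse(sizes <= 128, 3L, 4L)))
})

test_that("PDN features use exactly three extra convolutions at 7x7", {
  model <- bc_model(tiny_test_config())
  expect_length(grep("^pdn\\.c\\d\\.w$", names(model$params)), 3)
  bb <- backbone_forward(model, matrix(60, 128, 128))
  lv <- model_levels(model, bb)
  boxes_in <- rbind(c(10, 10, 40, 40), c(20, 30, 100, 110))
  ft <- pdn_features(model, lv$pdn, boxes_in)
  expect_equal(dim(ft$features)[c(1, 2, 4)], c(7, 7, 2))
  # zero conv weights collapse the deep features to zero
  for (i in 1:3) model$params[[sprintf("pdn.c%d.w", i)]][] <- 0
  ft0 <- pdn_features(model, lv$pdn, boxes_in)
  expect_true(all(ft0$features == 0))
})

test_that("retention requires the score to strictly exceed the threshold", {
  mk <- function(probs) {
    model <- model_with_fixed_pdn_scores(probs)
    cls <- pdn_classify(model, array(0, c(7, 7, 16, 4)))
    list(retained = cls$retained, label = cls$final_label,
         scores = cls$pdn_scores)
  }
  at_threshold <- mk(c(0.2, 0.3, 0.5))
  expect_equal(unique(at_threshold$label), 2L)
  expect_false(any(at_threshold$retained)) # 0.5 is not > 0.5
  clear <- mk(c(0.1, 0.1, 0.8))
  expect_true(all(clear$retained))
  background <- mk(c(0.8, 0.1, 0.1))
  expect_false(any(background$retained))
  benign <- mk(c(0.1, 0.8, 0.1))
  expect_true(all(benign$retained)) # benign retained under the same rule
  expect_equal(rowSums(clear$scores), rep(1, 4), tolerance = 1e-5)
})

test_that("dual-plane fusion is a logical OR with undetected propagation", {
  expect_equal(fuse_dual_plane(TRUE, FALSE), "malignant")
  expect_equal(fuse_dual_plane(FALSE, FALSE), "benign")
  # full 2 x 2 truth table
  grid <- expand.grid(ax = c(TRUE, FALSE), sag = c(TRUE, FALSE))
  expect_equal(fuse_dual_plane(grid$ax, grid$sag),
               ifelse(grid$ax | grid$sag, "malignant", "benign"))
  expect_equal(fuse_dual_plane(NA, TRUE), "malignant")
  expect_equal(fuse_dual_plane(NA, FALSE), "benign")
  expect_equal(fuse_dual_plane(NA, NA), "undetected")
})

test_that("perfect predictions give an exactly zero loss breakdown", {
  lb <- compute_losses(
    list(rpn_objectness = c(1, 0),
         rpn_deltas = matrix(0.3, 4, 4),
         roi_scores = diag(3)[c(1, 2, 3, 1), ],
         roi_deltas = matrix(-0.2, 3, 4),
         pdn_scores = diag(3)[c(3, 1, 2), ]),
    list(rpn_labels = c(1, 0),
         rpn_delta_targets = matrix(0.3, 4, 4),
         roi_labels = c(0L, 1L, 2L, 0L),
         roi_delta_targets = matrix(-0.2, 3, 4),
         pdn_labels = c(2L, 0L, 1L)))
  expect_true(all(unlist(lb) == 0))
})

test_that("cross-entropy terms match hand computation", {
  lb <- compute_losses(
    list(rpn_objectness = numeric(0), rpn_deltas = NULL,
         roi_scores = matrix(numeric(), 0, 3), roi_deltas = NULL,
         pdn_scores = matrix(c(0.1, 0.2, 0.7), 1)),
    list(rpn_labels = numeric(0), rpn_delta_targets = NULL,
         roi_labels = integer(0), roi_delta_targets = NULL,
         pdn_labels = 2L))
  expect_equal(lb$pdn_cls_loss, -log(0.7), tolerance = 1e-12)
  expect_equal(lb$total, -log(0.7))
})

test_that("the total is exactly the sum of the five terms on random inputs", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:20, 1); npos <- sample(1:3, 1)
    soft <- function(k) {
      z <- matrix(rexp(k * 3), k); z / rowSums(z)
    }
    lb <- compute_losses(
      list(rpn_objectness = runif(n), rpn_deltas = matrix(rnorm(npos * 4), npos),
           roi_scores = soft(n), roi_deltas = matrix(rnorm(npos * 4), npos),
           pdn_scores = soft(n)),
      list(rpn_labels = rbinom(n, 1, 0.4),
           rpn_delta_targets = matrix(rnorm(npos * 4), npos),
           roi_labels = sample(0:2, n, replace = TRUE),
           roi_delta_targets = matrix(rnorm(npos * 4), npos),
           pdn_labels = sample(0:2, n, replace = TRUE)))
    expect_identical(lb$total, lb$rpn_cls_loss + lb$rpn_loc_loss +
                       lb$roi_cls_loss + lb$roi_loc_loss + lb$pdn_cls_loss)
    expect_true(all(unlist(lb) >= 0))
  }
})

test_that("localization terms vanish with no positive samples, with a log line", {
  msgs <- capture_messages(
    lb <- compute_losses(
      list(rpn_objectness = c(0.5, 0.5), rpn_deltas = NULL,
           roi_scores = matrix(1 / 3, 2, 3), roi_deltas = NULL,
           pdn_scores = matrix(1 / 3, 2, 3)),
      list(rpn_labels = c(0, 0), rpn_delta_targets = NULL,
           roi_labels = c(0L, 0L), roi_delta_targets = NULL,
           pdn_labels = c(0L, 0L))))
  expect_equal(lb$rpn_loc_loss, 0)
  expect_equal(lb$roi_loc_loss, 0)
  expect_true(any(grepl("loc_positives=0", msgs)))
})
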