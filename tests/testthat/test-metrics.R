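# Evaluation metrics: confusion rates, AP at IoU 0.5, ROC/AUC, and the
# lesion-level tally.

test_that("confusion rates match their defining ratios", {
  r <- confusion_rates(list(TP = 19, FN = 1, FP = 8, TN = 52))
  expect_equal(r$sensitivity, 0.95)
  expect_equal(r$fpr, 8 / 60, tolerance = 1e-4)
  perfect <- confusion_rates(list(TP = 5, FN = 0, FP = 0, TN = 9))
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$fpr, 0)
  w <- capture_warnings(
    r0 <- confusion_rates(list(TP = 0, FN = 0, FP = 0, TN = 0)))
  expect_true(any(grepl("undefined", w)))
  expect_true(all(is.nan(unlist(r0))))
  expect_error(confusion_rates(list(TP = -1, FN = 0, FP = 0, TN = 0)))
  # complement identities whenever defined
  set.seed(4)
  for (i in 1:20) {
    counts <- as.list(setNames(sample(1:30, 4, TRUE), c("TP", "FP", "TN", "FN")))
    r <- confusion_rates(counts)
    expect_equal(r$sensitivity + counts$FN / (counts$TP + counts$FN), 1)
    expect_equal(r$fpr + r$specificity, 1)
  }
})

random_det_gt <- function(n_img = 4, seed) {
  set.seed(seed)
  gt <- purrr::map_dfr(seq_len(n_img), function(i) {
    k <- sample(1:3, 1)
    b <- t(vapply(seq_len(k), function(j) random_box(60), numeric(4)))
    tibble::tibble(image_id = paste0("im", i), x_min = b[, 1], y_min = b[, 2],
                   x_max = b[, 3], y_max = b[, 4],
                   label = sample(c("benign", "malignant"), k, TRUE),
                   lesion_id = paste0("L", i, "_", seq_len(k)))
  })
  det <- purrr::map_dfr(seq_len(nrow(gt)), function(j) {
    out <- NULL
    if (runif(1) < 0.8) { # jittered true detection
      jit <- unlist(gt[j, c("x_min", "y_min", "x_max", "y_max")]) + rnorm(4, 0, 2)
      jit[3] <- max(jit[3], jit[1] + 1); jit[4] <- max(jit[4], jit[2] + 1)
      out <- tibble::tibble(image_id = gt$image_id[j], x_min = jit[1],
                            y_min = jit[2], x_max = jit[3], y_max = jit[4],
                            label = gt$label[j], score = runif(1))
    }
    if (runif(1) < 0.3) { # a stray false positive
      b <- random_box(60)
      out <- dplyr::bind_rows(out, tibble::tibble(
        image_id = gt$image_id[j], x_min = b[1], y_min = b[2], x_max = b[3],
        y_max = b[4], label = sample(c("benign", "malignant"), 1),
        score = runif(1)))
    }
    out
  })
  list(det = det, gt = gt)
}

test_that("average precision handles the degenerate extremes", {
  gt <- tibble::tibble(image_id = "a", x_min = 0, y_min = 0, x_max = 10,
                       y_max = 10, label = "malignant")
  det <- dplyr::mutate(gt, score = 0.4)
  expect_equal(average_precision_50(det, gt, "malignant"), 1)
  expect_equal(average_precision_50(det[0, ], gt, "malignant"), 0)
  expect_warning(ap <- average_precision_50(det, gt, "benign"), "no ground truth")
  expect_true(is.na(ap))
  expect_equal(suppressWarnings(map50(det, gt)), 1) # benign AP excluded
})

test_that("average precision equals the threshold-enumeration oracle", {
  for (s in 1:40) {
    dd <- random_det_gt(3, seed = 200 + s)
    for (cl in c("benign", "malignant")) {
      gt_c <- dd$gt[dd$gt$label == cl, ]
      if (!nrow(gt_c)) next
      got <- average_precision_50(dd$det, dd$gt, cl)
      want <- oracle_ap(dd$det[dd$det$label == cl, ], gt_c)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("roc_auc matches the tie-aware pairwise oracle and its extremes", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  set.seed(31)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE) # plenty of ties
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    r <- roc_auc(sc, lab)
    expect_equal(r$auc, oracle_auc(sc, lab), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  }
})

test_that("lesion tally handles the perfect and empty extremes", {
  gt <- tibble::tibble(
    image_id = c("a", "a2", "b", "b2"),
    x_min = 10, y_min = 10, x_max = 30, y_max = 30,
    label = c("malignant", "malignant", "benign", "benign"),
    lesion_id = c("m1", "m1", "b1", "b1"))
  perfect <- dplyr::mutate(gt[c(1, 3), ], score = 0.9)
  perfect$label <- "malignant" # what a detector flags; benign row is an FP hit
  t1 <- lesion_level_tally(perfect[1, ], gt)
  expect_equal(unlist(t1), c(TP = 1, FP = 0, TN = 1, FN = 0))
  t0 <- lesion_level_tally(perfect[0, ], gt)
  expect_equal(unlist(t0), c(TP = 0, FP = 0, TN = 1, FN = 1))
  expect_error(lesion_level_tally(
    dplyr::mutate(perfect, image_id = "zz"), gt), "unknown image")
})

test_that("lesion tally matches a hand enumeration with planted mistakes", {
  # ten lesions over two planes: 6 malignant, 4 benign
  gt <- purrr::map_dfr(1:10, function(i) tibble::tibble(
    image_id = c(paste0("c", i, "_ax"), paste0("c", i, "_sag")),
    x_min = 20, y_min = 20, x_max = 50, y_max = 50,
    label = if (i <= 6) "malignant" else "benign",
    lesion_id = paste0("les", i)))
  det <- purrr::map_dfr(1:10, function(i) {
    if (i == 3) return(NULL)            # planted miss -> FN
    if (i > 6 && i != 8) return(NULL)   # benign mostly undetected -> TN
    tibble::tibble(image_id = paste0("c", i, "_ax"), x_min = 21, y_min = 21,
                   x_max = 51, y_max = 51, label = "malignant", score = 0.9)
  })
  # planted stray detections: two overlapping boxes in one image -> 1 FP
  det <- dplyr::bind_rows(det, tibble::tibble(
    image_id = "c1_sag", x_min = c(80, 85), y_min = c(80, 85),
    x_max = c(100, 105), y_max = c(100, 105), label = "malignant",
    score = c(0.7, 0.6)))
  tally <- lesion_level_tally(det, gt)
  # hand count: malignant hits 1,2,4,5,6 (TP=5), miss 3 (FN=1);
  # benign 8 hit by a malignant call (FP=1), 7,9,10 clean (TN=3);
  # one stray cluster (FP+1)
  expect_equal(unlist(tally), c(TP = 5, FP = 2, TN = 3, FN = 1))
  rates <- confusion_rates(tally)
  expect_equal(rates$sensitivity, 5 / 6)
})
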