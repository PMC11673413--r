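# Phantom generator: determinism, ground-truth consistency, dataset layout,
# and the roughness statistic separating the two lesion shapes.

test_that("case generation is deterministic in (seed, case_index)", {
  spec <- phantom_spec(seed = 5)
  a <- generate_case(spec, 3)
  b <- generate_case(spec, 3)
  expect_identical(a$axial_image, b$axial_image)
  expect_identical(a$sagittal_image, b$sagittal_image)
  expect_identical(a$axial_annotations, b$axial_annotations)
  c <- generate_case(spec, 4)
  expect_false(identical(a$axial_image, c$axial_image))
})

test_that("malignant_fraction 0 yields only benign lesions", {
  spec <- phantom_spec(seed = 2, malignant_fraction = 0)
  for (i in 1:5) {
    cs <- generate_case(spec, i)
    expect_true(all(cs$lesions$label == "benign"))
    expect_true(all(cs$axial_annotations$label == "benign"))
  }
})

test_that("lesions appear in both planes with shared ids and valid boxes", {
  spec <- phantom_spec(seed = 8, lesions_per_case = c(1, 2),
                       benign_radius_range = c(4, 6),
                       malignant_radius_range = c(4, 6))
  for (i in 1:6) {
    cs <- generate_case(spec, i)
    expect_setequal(cs$axial_annotations$lesion_id,
                    cs$sagittal_annotations$lesion_id)
    expect_equal(cs$axial_annotations$label[
                   order(cs$axial_annotations$lesion_id)],
                 cs$sagittal_annotations$label[
                   order(cs$sagittal_annotations$lesion_id)])
    validate_boxes(cs$axial_annotations)
    validate_boxes(cs$sagittal_annotations)
  }
})

test_that("annotation boxes stay inside the dilated breast mask", {
  spec <- phantom_spec(seed = 13)
  brush <- EBImage::makeBrush(5, "disc")
  for (i in 1:8) {
    cs <- generate_case(spec, i)
    for (plane in c("axial", "sagittal")) {
      mask <- if (plane == "axial") cs$axial_breast_mask else cs$sagittal_breast_mask
      dil <- as.matrix(EBImage::dilate(EBImage::Image(mask), brush))
      ann <- if (plane == "axial") cs$axial_annotations else cs$sagittal_annotations
      for (j in seq_len(nrow(ann))) {
        rows <- (floor(ann$y_min[j]) + 1):ceiling(ann$y_max[j])
        cols <- (floor(ann$x_min[j]) + 1):ceiling(ann$x_max[j])
        expect_true(all(dil[rows, cols] > 0))
      }
    }
  }
})

test_that("the corner block mean tracks the background offset", {
  spec <- phantom_spec(seed = 29)
  devs <- vapply(1:20, function(i) {
    cs <- generate_case(spec, i)
    mean(c(mean(cs$axial_image[1:4, 1:4]), mean(cs$sagittal_image[1:4, 1:4])))
  }, numeric(1))
  expect_true(all(abs(devs - spec$background_offset) <= 3 * spec$noise_sd / 4))
})

test_that("rendered lesion centers agree with the declared quadrant truth", {
  spec <- phantom_spec(seed = 41)
  n_checked <- 0
  for (i in 1:200) {
    cs <- generate_case(spec, i)
    for (j in seq_len(nrow(cs$lesions))) {
      lid <- cs$lesions$lesion_id[j]
      ax <- cs$axial_annotations[cs$axial_annotations$lesion_id == lid, ]
      sg <- cs$sagittal_annotations[cs$sagittal_annotations$lesion_id == lid, ]
      q <- locate_quadrant(unlist(box_center(sg)), unlist(box_center(ax)),
                           cs$geometry)
      expect_equal(q, cs$lesions$quadrant[j])
      expect_equal(laterality(box_center(ax)$x, cs$geometry),
                   cs$lesions$laterality[j])
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
})

test_that("class balance converges to malignant_fraction", {
  spec <- phantom_spec(seed = 3, lesions_per_case = c(2, 2),
                       malignant_fraction = 0.5,
                       benign_radius_range = c(4, 6),
                       malignant_radius_range = c(4, 6))
  # cramped multi-lesion cases can fail placement and are skipped
  labs <- unlist(lapply(1:270, function(i)
    tryCatch(generate_case(spec, i)$lesions$label, error = function(e) NULL)))
  expect_gte(length(labs), 500)
  p_hat <- mean(labs == "malignant")
  ci <- 1.96 * sqrt(0.25 / length(labs))
  expect_lt(abs(p_hat - 0.5), ci + 0.03)
})

test_that("dataset writer emits the VOC layout with a stable manifest", {
  dir <- phantom_dataset_dir(20, seed = 19)
  expect_length(list.files(file.path(dir, "JPEGImages")), 40)
  expect_length(list.files(file.path(dir, "Annotations")), 40)
  m1 <- read.csv(file.path(dir, "manifest.csv"))
  expect_true(all(m1$label %in% c("benign", "malignant")))
  expect_setequal(unique(m1$split), c("train", "val", "test"))
  dir2 <- tempfile()
  m2 <- generate_dataset(phantom_spec(seed = 19, n_cases = 20), dir2)
  expect_equal(as.data.frame(m2), m1)
  splits <- readLines(file.path(dir, "ImageSets", "Main", "train.txt"))
  expect_true(all(file.exists(file.path(dir, "JPEGImages",
                                        paste0(splits, ".png")))))
})

test_that("boundary roughness separates spiculated from smooth masks", {
  g <- pixel_grid(64, 64)
  disk <- (g$X - 32)^2 + (g$Y - 32)^2 <= 20^2
  expect_lt(abs(boundary_roughness(disk) - 1), 0.1)
  sq <- matrix(0, 64, 64); sq[17:46, 17:46] <- 1
  expect_lt(abs(boundary_roughness(sq) - 4 / pi), 0.1)
  expect_error(boundary_roughness(matrix(0, 10, 10)), "empty")
  # generated malignant lesions are strictly rougher on average
  spec <- phantom_spec(seed = 57)
  rough <- list(benign = c(), malignant = c())
  i <- 0
  while (length(rough$benign) + length(rough$malignant) < 100) {
    i <- i + 1
    cs <- generate_case(spec, i)
    for (j in seq_len(nrow(cs$lesions)))
      rough[[cs$lesions$label[j]]] <- c(
        rough[[cs$lesions$label[j]]],
        boundary_roughness(cs$axial_lesion_masks[[cs$lesions$lesion_id[j]]]))
  }
  expect_gt(mean(rough$malignant), mean(rough$benign))
  expect_gt(mean(rough$malignant), 2) # strongly spiculated by construction
  expect_lt(mean(rough$benign), 1.3)
})
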