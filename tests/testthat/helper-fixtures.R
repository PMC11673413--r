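# Shared fixtures, generated once per test session. Internal helpers the
# tests poke at directly are aliased here.

box_matrix <- bcrcnn:::box_matrix
validate_boxes <- bcrcnn:::validate_boxes
pixel_grid <- bcrcnn:::pixel_grid
bc_step <- bcrcnn:::bc_step
model_levels <- bcrcnn:::model_levels
conv_fw <- bcrcnn:::conv_fw
backbone_layout <- bcrcnn:::backbone_layout
fpn_level_scales <- bcrcnn:::fpn_level_scales
sag_to_anatomical <- bcrcnn:::sag_to_anatomical
QUADRANTS <- bcrcnn:::QUADRANTS
VOC_CLASSES <- bcrcnn:::VOC_CLASSES

phantom_dataset_dir <- local({
  cache <- new.env(parent = emptyenv())
  function(n_cases, seed = 11, ...) {
    key <- paste0("d", n_cases, "_", seed, "_",
                  paste(unlist(list(...)), collapse = "_"))
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("phantom_", key))
      if (!dir.exists(dir))
        generate_dataset(phantom_spec(seed = seed, n_cases = n_cases, ...), dir)
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})

tiny_test_config <- function(...) {
  bc_config(backbone_preset = "tiny", use_fpn = TRUE, short_side = 128,
            learning_rate = 0.01, ...)
}

random_box <- function(lim = 100, integer = FALSE) {
  r <- function() sort(runif(2, 0, lim))
  x <- r(); y <- r()
  b <- c(x[1], y[1], x[2], y[2])
  if (integer) {
    b <- c(floor(b[1]), floor(b[2]), ceiling(b[3]), ceiling(b[4]))
    if (b[3] == b[1]) b[3] <- b[1] + 1
    if (b[4] == b[2]) b[4] <- b[2] + 1
  }
  b
}

# a model whose PDN final layer emits fixed class probabilities
model_with_fixed_pdn_scores <- function(probs) {
  model <- bc_model(tiny_test_config())
  model$params[["pdn.fc.w"]][] <- 0
  model$params[["pdn.fc.b"]] <- log(probs)
  model
}
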