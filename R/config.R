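# Run configuration. Training constants default to the published recipe:
# IoU threshold 0.5, batch size 1, weight decay 5e-4, initial learning rate
# 1e-5, 30 epochs of SGD with momentum 0.9, 300 ROI candidates, 7x7 pooling,
# canonical ROI size 160, malignant retention threshold 0.5.

bc_config_defaults <- function() {
  list(
    num_classes = 3L,          # background, benign, malignant
    num_candidates = 300L,
    iou_threshold = 0.5,
    batch_size = 1L,
    weight_decay = 5e-4,
    learning_rate = 1e-5,
    epochs = 30L,
    momentum = 0.9,
    use_fpn = TRUE,
    canonical_roi_size = 160L,
    pooled_size = 7L,
    malignant_threshold = 0.5,
    backbone_preset = "vgg16",
    seed = 1L,
    # knobs the published recipe leaves at the standard two-stage defaults
    short_side = 512L,
    rpn_nms_threshold = 0.7,
    detect_nms_threshold = 0.3,
    rpn_pos_iou = 0.5,
    rpn_neg_iou = 0.3,
    rpn_batch = 128L,
    roi_batch = 128L,
    pre_nms_top_n = 1000L,
    grad_clip = 10,
    anchor_scales = c(128, 256, 512), # single-level mode
    fpn_base_scales = c(32, 64, 128, 256, 512),
    anchor_ratios = c(0.5, 1, 2)
  )
}

#' Build a run configuration
#'
#' Returns the full configuration with any overrides applied and validated.
#' Defaults follow the training recipe: IoU threshold 0.5, batch size 1,
#' weight decay 5e-4, learning rate 1e-5, 30 epochs of SGD with momentum 0.9,
#' 300 ROI candidates, 7x7 ROI pooling, canonical ROI size 160 for pyramid
#' level assignment, and a 0.5 malignant retention threshold.
#'
#' @param ... named overrides; unknown names are an error.
#' @return An object of class `bc_config` (a named list).
#' @examples
#' cfg <- bc_config(backbone_preset = "tiny", epochs = 5)
#' cfg$momentum
#' @export
bc_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) && is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  defaults <- bc_config_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, overrides)
  for (k in c("num_classes", "num_candidates", "batch_size", "epochs",
              "canonical_roi_size", "pooled_size", "seed", "short_side",
              "rpn_batch", "roi_batch", "pre_nms_top_n"))
    cfg[[k]] <- as.integer(cfg[[k]])
  validate_config(cfg)
  structure(cfg, class = "bc_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$num_classes >= 2L,
            cfg$num_candidates >= 1L,
            cfg$malignant_threshold > 0, cfg$malignant_threshold < 1,
            cfg$iou_threshold > 0, cfg$iou_threshold <= 1,
            cfg$batch_size >= 1L, cfg$epochs >= 1L,
            cfg$momentum >= 0, cfg$momentum < 1,
            cfg$learning_rate > 0, cfg$weight_decay >= 0,
            cfg$pooled_size >= 1L, cfg$canonical_roi_size >= 1L,
            cfg$short_side >= 1L)
  if (!cfg$backbone_preset %in% c("vgg16", "tiny"))
    stop("backbone_preset must be 'vgg16' or 'tiny'")
  invisible(cfg)
}

#' Load a configuration from a flat YAML file
#'
#' The file holds flat `key: value` pairs; keys must be configuration fields.
#' Explicit arguments override file values. The resulting configuration is
#' echoed to the log, one `key=value` line per field.
#'
#' @param path optional YAML file; `NULL` uses defaults only.
#' @param ... named overrides applied after the file.
#' @return A [bc_config()] object.
#' @export
load_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("configuration file must hold key: value pairs")
  }
  vals <- modifyList(vals, list(...))
  cfg <- bc_config(vals)
  for (k in names(cfg))
    bc_log(k, paste(format(cfg[[k]], trim = TRUE), collapse = ","))
  cfg
}

# Structured key=value log lines on stderr.
bc_log <- function(key, value) {
  message(sprintf("%s=%s", key, value))
}

#' @export
print.bc_config <- function(x, ...) {
  cat("<bc_config>\n")
  for (k in names(x))
    cat(sprintf("  %s: %s\n", k, paste(format(x[[k]], trim = TRUE), collapse = ", ")))
  invisible(x)
}
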