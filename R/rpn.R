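# Region proposal network. Anchors use the three width-to-height ratios
# 1:2, 1:1, 2:1. In single-level mode the head sees 3 scales x 3 ratios = 9
# anchor shapes per location (the classic configuration); in pyramid mode
# each level carries one base scale from {32, 64, 128, 256, 512} realized as
# the two geometric neighbors {s / sqrt(2), s * sqrt(2)}, giving 2 x 3 = 6
# shapes per location per level.

fpn_level_scales <- function(base) c(base / sqrt(2), base * sqrt(2))

# anchor grids depend only on (shape, stride, scales, ratios); memoized as
# plain matrices since they are rebuilt for every forward pass
.anchor_cache <- new.env(parent = emptyenv())

anchor_grid_matrix <- function(feature_shape, stride, scales, ratios) {
  key <- paste(c(feature_shape, stride, scales, ratios), collapse = "|")
  hit <- .anchor_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- box_matrix(build_anchor_grid(feature_shape, stride, scales, ratios))
  .anchor_cache[[key]] <- m
  m
}

#' Build the anchor grid for one feature map
#'
#' One anchor per (location, shape): anchors are centered on feature-map
#' cell centers times the stride, and the shape for `(scale, ratio)` has
#' area `scale^2` and width/height ratio `ratio`. Row order matches the
#' column-major flattening of the `[H, W, A]` head outputs (rows fastest,
#' then columns, then shapes).
#'
#' @param feature_shape integer `c(H, W)` of the feature map.
#' @param stride feature-map stride in image pixels.
#' @param scales numeric vector of anchor scales (sqrt of anchor area).
#' @param ratios width-to-height ratios; defaults to `c(0.5, 1, 2)`.
#' @return A box tibble with `nrow = H * W * length(scales) * length(ratios)`
#'   and columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
build_anchor_grid <- function(feature_shape, stride, scales,
                              ratios = c(0.5, 1, 2)) {
  if (!length(scales)) stop("scales must be non-empty")
  h <- feature_shape[1]; w <- feature_shape[2]
  shapes <- expand.grid(ratio = ratios, scale = scales) # ratio fastest
  aw <- shapes$scale * sqrt(shapes$ratio)
  ah <- shapes$scale / sqrt(shapes$ratio)
  grid <- expand.grid(i = seq_len(h) - 0.5, j = seq_len(w) - 0.5)
  cx <- rep(grid$j * stride, times = nrow(shapes))
  cy <- rep(grid$i * stride, times = nrow(shapes))
  w2 <- rep(aw, each = nrow(grid)) / 2
  h2 <- rep(ah, each = nrow(grid)) / 2
  boxes(cx - w2, cy - h2, cx + w2, cy + h2)
}

# head layers use the small Gaussian init customary for two-stage
# detectors (keeps early deltas near zero and objectness near chance)
init_rpn_params <- function(channels, n_shapes) {
  list("rpn.conv.w" = array(rnorm(9 * channels^2, sd = 0.01),
                            c(3, 3, channels, channels)),
       "rpn.conv.b" = numeric(channels),
       "rpn.cls.w" = array(rnorm(channels * n_shapes, sd = 0.01),
                           c(1, 1, channels, n_shapes)),
       "rpn.cls.b" = numeric(n_shapes),
       "rpn.reg.w" = array(rnorm(channels * 4 * n_shapes, sd = 0.01),
                           c(1, 1, channels, 4L * n_shapes)),
       "rpn.reg.b" = numeric(4L * n_shapes))
}

#' RPN forward pass over one or more feature levels
#'
#' A shared 3x3 convolution with ReLU followed by two 1x1 heads per level:
#' per-anchor objectness logits and per-anchor box regression deltas.
#'
#' @param model a `bc_rcnn_model`.
#' @param levels named list of `list(map, stride)` feature levels.
#' @return Per level: objectness logits (vector, anchor order), deltas
#'   (`n x 4` matrix), the anchor tibble, and caches.
#' @export
rpn_forward <- function(model, levels) {
  params <- model$params
  cfg <- model$config
  out <- list()
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    scales <- if (cfg$use_fpn)
      fpn_level_scales(cfg$fpn_base_scales[match(nm, c("P2", "P3", "P4", "P5", "P6"))])
    else cfg$anchor_scales
    anchors <- anchor_grid_matrix(dim(lv$map)[1:2], lv$stride, scales,
                                  cfg$anchor_ratios)
    cv <- conv_fw(lv$map, params[["rpn.conv.w"]], params[["rpn.conv.b"]])
    rl <- relu_fw(cv$y)
    cls <- conv_fw(rl$y, params[["rpn.cls.w"]], params[["rpn.cls.b"]])
    reg <- conv_fw(rl$y, params[["rpn.reg.w"]], params[["rpn.reg.b"]])
    n_shapes <- dim(params[["rpn.cls.w"]])[4]
    hw <- prod(dim(lv$map)[1:2])
    out[[nm]] <- list(
      objectness = as.vector(cls$y),
      deltas = matrix(aperm(array(reg$y, c(hw, 4L, n_shapes)), c(1, 3, 2)),
                      ncol = 4L),
      anchors = anchors,
      cache = list(conv = cv, relu = rl, cls = cls, reg = reg,
                   map_dim = dim(lv$map), n_shapes = n_shapes))
  }
  out
}

# Backward for one level given gradients on objectness (vector) and deltas
# (n x 4). Returns the gradient with respect to the level's feature map.
rpn_backward_level <- function(cache, g_obj, g_deltas, ge) {
  hw <- prod(cache$map_dim[1:2]); A <- cache$n_shapes
  g_cls <- array(g_obj, c(cache$map_dim[1:2], A))
  g_reg_arr <- aperm(array(g_deltas, c(hw, A, 4L)), c(1, 3, 2))
  g_reg <- array(g_reg_arr, c(cache$map_dim[1:2], 4L * A))
  bw_cls <- conv_bw(cache$cls, g_cls)
  bw_reg <- conv_bw(cache$reg, g_reg)
  grad_add(ge, "rpn.cls.w", bw_cls$gw); grad_add(ge, "rpn.cls.b", bw_cls$gb)
  grad_add(ge, "rpn.reg.w", bw_reg$gw); grad_add(ge, "rpn.reg.b", bw_reg$gb)
  g <- relu_bw(cache$relu, bw_cls$gx + bw_reg$gx)
  bw <- conv_bw(cache$conv, g)
  grad_add(ge, "rpn.conv.w", bw$gw); grad_add(ge, "rpn.conv.b", bw$gb)
  bw$gx
}

#' Generate proposals from RPN outputs
#'
#' Decodes per-anchor deltas, clips to the image, drops boxes with a side
#' under 2 px, applies NMS at `rpn_nms_threshold`, and keeps the top
#' `num_candidates` by objectness. When fewer survive, the lowest-scored
#' kept proposal is repeated to preserve the fixed candidate count.
#'
#' @param rpn_out result of [rpn_forward()].
#' @param image_size integer `c(width, height)`.
#' @param config a [bc_config()].
#' @return A tibble of `num_candidates` rows: box columns plus `objectness`,
#'   sorted by descending objectness.
#' @export
propose <- function(rpn_out, image_size, config) {
  # top pre_nms_top_n anchors by objectness across all levels, then decode
  sc_all <- lapply(rpn_out, `[[`, "objectness")
  sc <- unlist(sc_all, use.names = FALSE)
  keep <- seq_along(sc)
  if (length(sc) > config$pre_nms_top_n)
    keep <- order(sc, decreasing = TRUE)[seq_len(config$pre_nms_top_n)]
  lens <- vapply(sc_all, length, 1L)
  lvl_of <- rep(seq_along(lens), lens)
  offs <- cumsum(c(0L, lens))
  all_boxes <- matrix(0, length(keep), 4)
  all_scores <- sc[keep]
  for (li in unique(lvl_of[keep])) {
    rows <- which(lvl_of[keep] == li)
    local_idx <- keep[rows] - offs[li]
    lv <- rpn_out[[li]]
    dec <- decode_deltas(box_matrix(lv$anchors)[local_idx, , drop = FALSE],
                         lv$deltas[local_idx, , drop = FALSE],
                         width = image_size[1], height = image_size[2])
    all_boxes[rows, ] <- box_matrix(dec)
  }
  wide <- (all_boxes[, 3] - all_boxes[, 1]) >= 2 &
          (all_boxes[, 4] - all_boxes[, 2]) >= 2
  if (!any(wide)) {
    # every decoded box degenerated (possible for an untrained RPN): fall
    # back to the clipped anchors themselves
    anch <- do.call(rbind, lapply(rpn_out, function(o) box_matrix(o$anchors)))
    all_boxes <- clip_boxes(anch[keep, , drop = FALSE],
                            image_size[1], image_size[2])
    wide <- (all_boxes[, 3] - all_boxes[, 1]) >= 2 &
            (all_boxes[, 4] - all_boxes[, 2]) >= 2
  }
  all_boxes <- all_boxes[wide, , drop = FALSE]
  all_scores <- all_scores[wide]
  if (!nrow(all_boxes))
    stop("no valid proposals; degenerate RPN output")
  keep <- as.integer(nms_cpp(all_boxes, all_scores, config$rpn_nms_threshold,
                             config$num_candidates))
  boxes_kept <- all_boxes[keep, , drop = FALSE]
  scores_kept <- all_scores[keep]
  if (length(keep) < config$num_candidates) {
    pad <- config$num_candidates - length(keep)
    last <- length(keep)
    boxes_kept <- rbind(boxes_kept,
                        boxes_kept[rep(last, pad), , drop = FALSE])
    scores_kept <- c(scores_kept, rep(scores_kept[last], pad))
  }
  out <- box_tibble(boxes_kept)
  out$objectness <- sigmoid(scores_kept)
  out
}
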