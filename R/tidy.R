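# broom-style accessors and ggplot2 autoplot methods.

#' Tidy a trained model's loss history
#'
#' One row per epoch and loss term, in long format.
#'
#' @param x a `bc_rcnn_model`.
#' @param ... unused.
#' @return A tibble with `epoch`, `term`, `value`.
#' @export
tidy.bc_rcnn_model <- function(x, ...) {
  if (is.null(x$loss_history)) stop("model has not been trained")
  tidyr::pivot_longer(x$loss_history, -"epoch", names_to = "term",
                      values_to = "value")
}

#' One-row summary of a trained model
#'
#' @param x a `bc_rcnn_model`.
#' @param ... unused.
#' @return A tibble with the preset, parameter count, epochs trained, and
#'   final/best losses.
#' @export
glance.bc_rcnn_model <- function(x, ...) {
  h <- x$loss_history
  tibble::tibble(
    backbone = x$config$backbone_preset,
    use_fpn = x$config$use_fpn,
    n_parameters = sum(vapply(x$params, length, 1)),
    epochs = if (is.null(h)) 0L else max(h$epoch),
    final_train_loss = if (is.null(h)) NA_real_ else h$total[nrow(h)],
    best_val_loss = if (is.null(h)) NA_real_ else suppressWarnings(min(h$val_total, na.rm = TRUE)))
}

#' Plot the training loss history
#'
#' @param object a trained `bc_rcnn_model`.
#' @param ... unused.
#' @return A ggplot: loss terms against epochs.
#' @export
autoplot.bc_rcnn_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot detections over a slice
#'
#' @param image numeric matrix (the slice the detections refer to).
#' @param detections detection tibble (box columns, `label`, `score`).
#' @param ground_truth optional ground-truth box tibble drawn dashed.
#' @return A ggplot with the slice as a raster and boxes colored by class.
#' @export
plot_detections <- function(image, detections, ground_truth = NULL) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(image)) - 0.5, each = nrow(image)),
    y = rep(seq_len(nrow(image)) - 0.5, ncol(image)),
    value = as.vector(image))
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(ground_truth) && nrow(ground_truth))
    p <- p + ggplot2::geom_rect(
      data = ground_truth,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      fill = NA, colour = "white", linetype = "dashed")
  if (nrow(detections))
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max,
                   colour = .data$label),
      fill = NA, linewidth = 0.7)
  p + ggplot2::labs(colour = NULL)
}
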