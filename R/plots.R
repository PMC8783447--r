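#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contour intensity profile
#'
#' Segment index against net mean intensity, with the high/low/mid levels
#' and the +/- p% discontinuity band overlaid — the visual counterpart of
#' the phase-separation decision.
#'
#' @param object a [contour_profile()].
#' @param percentile,p parameters of the decision (see [domain_levels()]
#'   and [detect_discontinuities()]).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot contour_profile
#' @export
autoplot.contour_profile <- function(object, percentile = 20, p = 20, ...) {
  lev <- domain_levels(object, percentile)
  df <- tibble::tibble(segment = seq_len(object$N) - 1L,
                       intensity = object$segment_means)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$segment,
                                         y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = lev$mid, linetype = 2) +
    ggplot2::labs(x = sprintf("contour segment (of %d)", object$N),
                  y = "net intensity per px")
  if (lev$mid > 0) {
    band <- tibble::tibble(ymin = lev$mid * (1 - p / 100),
                           ymax = lev$mid * (1 + p / 100))
    gg <- gg + ggplot2::geom_rect(
      data = band, inherit.aes = FALSE,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$ymin,
                   ymax = .data$ymax), alpha = 0.15)
  }
  gg
}

#' Plot the training history of a classifier
#'
#' Validation accuracy and loss per validation evaluation.
#'
#' @param object a `guv_cnn`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot guv_cnn
#' @export
autoplot.guv_cnn <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history[c("iteration", "val_acc",
                                             "val_loss")],
                            cols = c("val_acc", "val_loss"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}

#' Plot detections over a section image
#'
#' @param stack a [guv_stack()].
#' @param detections tibble with `z_index`, `cx`, `cy`, `r` (optionally
#'   `class` or `pass` for coloring).
#' @param z_index which section to show (0-based).
#' @return A ggplot.
#' @export
plot_detections <- function(stack, detections, z_index = 0L) {
  img <- stack$sections[[z_index + 1L]]
  df <- tibble::tibble(
    x = rep(0:(ncol(img) - 1), each = nrow(img)),
    y = rep(0:(nrow(img) - 1), times = ncol(img)),
    intensity = as.numeric(img))
  rows <- detections[detections$z_index == z_index, , drop = FALSE]
  color_col <- if ("class" %in% names(rows)) "class"
  else if ("pass" %in% names(rows)) "pass" else NULL
  circ <- tidyr::crossing(rows, theta = seq(0, 2 * pi, length.out = 90))
  circ <- dplyr::mutate(circ, px = .data$cx + .data$r * cos(.data$theta),
                        py = .data$cy + .data$r * sin(.data$theta))
  gg <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (nrow(circ) > 0) {
    mapping <- if (is.null(color_col)) {
      ggplot2::aes(x = .data$px, y = .data$py,
                   group = interaction(.data$cx, .data$cy, .data$r))
    } else {
      ggplot2::aes(x = .data$px, y = .data$py,
                   group = interaction(.data$cx, .data$cy, .data$r),
                   color = .data[[color_col]])
    }
    gg <- gg + ggplot2::geom_path(data = circ, mapping = mapping)
  }
  gg
}
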