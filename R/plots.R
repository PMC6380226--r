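#' Plot a direction-preference map
#'
#' Quiver-style map of the sheet: one arrow per neuron pointing along its
#' preferred direction, scaled by its peak response, over colour patches of
#' the preferred direction.
#'
#' @param x a `direction_map`.
#' @param arrow_scale arrow length (sheet units) at peak response 1.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.direction_map <- function(x, arrow_scale = 0.45, ...) {
  th <- x$preferred_deg * pi / 180
  df <- tibble(row = x$row, col = x$col,
               preferred = factor(x$preferred_deg),
               xend = x$col + arrow_scale * x$peak * cos(th),
               yend = x$row - arrow_scale * x$peak * sin(th))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$preferred), alpha = 0.55) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.04, "in")),
      linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "preferred (deg)", x = NULL, y = NULL,
                  title = "Direction-preference map") +
    ggplot2::theme_minimal()
}

#' @rdname plot.direction_map
#' @param object a `direction_map`.
#' @export
autoplot.direction_map <- function(object, ...) plot.direction_map(object, ...)

#' Plot a robustness curve
#'
#' Robustness index versus noise level (or bar length).
#'
#' @param x a `robustness_curve`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.robustness_curve <- function(x, ...) {
  xvar <- if ("level" %in% names(x)) "level" else "length"
  ggplot2::ggplot(x, ggplot2::aes(x = .data[[xvar]], y = .data$ri)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = switch(attr(x, "noise_kind"),
                             salt_pepper = "noise density",
                             gaussian = "noise variance",
                             bar_length = "bar length (px)",
                             xvar),
                  y = "robustness index",
                  title = "Robustness of the preference map") +
    ggplot2::theme_minimal()
}

#' @rdname plot.robustness_curve
#' @param object a `robustness_curve`.
#' @export
autoplot.robustness_curve <- function(object, ...) plot.robustness_curve(object, ...)

#' Plot stimulus frames
#'
#' Small-multiple view of a stimulus sequence's frames.
#'
#' @param x a `stimulus_sequence`.
#' @param frames which frames to show (default all, up to 8).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.stimulus_sequence <- function(x, frames = NULL, ...) {
  frames <- frames %||% seq_len(min(length(x$frames), 8))
  df <- do.call(rbind, lapply(frames, function(t) {
    f <- x$frames[[t]]
    tibble(frame = t,
           row = rep(seq_len(nrow(f)), times = ncol(f)),
           col = rep(seq_len(ncol(f)), each = nrow(f)),
           value = as.vector(f))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~frame, nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s, %s deg", x$kind,
                                  format(x$direction_deg))) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none",
                   plot.title = ggplot2::element_text(size = 10))
}

#' Plot field activity as a bubble
#'
#' Heatmap of a settled-activity vector over the sheet.
#'
#' @param eta settled activity vector (length `dim^2`, column-major).
#' @param dim sheet side length.
#' @return a ggplot object.
#' @export
plot_activity <- function(eta, dim = sqrt(length(eta))) {
  df <- tibble(row = rep(seq_len(dim), times = dim),
               col = rep(seq_len(dim), each = dim),
               activity = eta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activity")
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
ggplot2::autoplot
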