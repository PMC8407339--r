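#' Volcano-style overview of a screen
#'
#' Mean LPI against `-log10` adjusted p value, coloured by call, with the
#' control-envelope bounds drawn as dashed lines. Non-grower rescues and
#' basal-dead strains have no p value and are omitted.
#'
#' @param object A `"screen_calls"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_calls <- function(object, ...) {
  env <- attr(object, "envelope")
  d <- tidy(object) |> dplyr::filter(is.finite(.data$p_adj))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_lpi,
                                  y = -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(env$t_tolerant, env$t_sensitive),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(
      tolerant = "#2166ac", sensitive = "#b2182b", unchanged = "grey60")) +
    ggplot2::labs(x = "mean LPI (log2 relative generation time, stress - basal)",
                  y = expression(-log[10] ~ "adjusted P"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plate heatmap of a spatial surface or bias field
#'
#' @param surface Either a matrix (rows x cols) or a tibble with `row`,
#'   `col` and a value column.
#' @param value Name of the value column when `surface` is a tibble.
#' @return A ggplot.
#' @export
plot_plate_surface <- function(surface, value = "control_gt") {
  d <- if (is.matrix(surface)) {
    tibble::tibble(row = as.vector(base::row(surface)) - 1L,
                   col = as.vector(base::col(surface)) - 1L,
                   value = as.vector(surface))
  } else {
    tibble::tibble(row = surface$row, col = surface$col,
                   value = surface[[value]])
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot growth curves on a log2 scale
#'
#' @param curves Long curve tibble (`time_h`, `value` plus colony keys).
#' @param colour Optional column name to colour by (e.g. `"condition"`).
#' @return A ggplot.
#' @export
plot_growth_curves <- function(curves, colour = NULL) {
  keys <- colony_keys(curves)
  curves$.colony <- do.call(paste, c(curves[keys], sep = "/"))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$time_h, y = log2(.data$value),
                                    group = .data$.colony))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_line(alpha = 0.5, colour = "grey30")
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]), alpha = 0.7)
  }
  p + ggplot2::labs(x = "time (h)", y = expression(log[2] ~ "population proxy")) +
    ggplot2::theme_minimal()
}
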