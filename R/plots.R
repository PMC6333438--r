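#' Plot a stiffness map
#'
#' Raster of K over the grid; missing nodes are blank.
#'
#' @param object A [stiffness_map].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stiffness_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$K_Pa)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "K (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm, rostral → caudal)",
                  y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a stiffness series as a frame montage
#'
#' @param object A [stiffness_series].
#' @param ... Unused.
#' @return A ggplot faceted by frame time.
#' @export
autoplot.stiffness_series <- function(object, ...) {
  df <- tidy(object)
  df$K_Pa[!df$observed] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$K_Pa)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "K (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~t_min, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a kinetics fit
#'
#' Rescaled series with the fitted line and extrapolated onset.
#'
#' @param object A `kinetics_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$rescaled)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$in_fit),
                        show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::geom_vline(xintercept = object$onset_min, colour = "red") +
    ggplot2::labs(x = "time (min)", y = "rescaled value",
                  title = sprintf("%s onset %.1f min (R² = %.3f)",
                                  object$kind, object$onset_min,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a Sholl profile
#'
#' @param object A `sholl_result`.
#' @param ... Unused.
#' @return A ggplot of crossings vs radius with the median reach marked.
#' @export
autoplot.sholl_result <- function(object, ...) {
  med <- suppressWarnings(median_sholl_radius(object))
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$radius_um, .data$crossings)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = med, linetype = 2, colour = "red") +
    ggplot2::labs(x = "radius (µm)", y = "intersections") +
    ggplot2::theme_minimal()
}

#' Plot a gradient time series
#'
#' @param data Tibble from [gradient_series()].
#' @return A ggplot of the gradient vs time.
#' @export
plot_gradient_series <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$t_min,
                                     .data$gradient_Pa_per_um)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "stiffness gradient (Pa/µm)") +
    ggplot2::theme_minimal()
}
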