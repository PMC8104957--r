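# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a visual-field canvas
#'
#' Heat map in visual-field coordinates (azimuth rightward, elevation up).
#'
#' @param object A [visual_field_canvas()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.visual_field_canvas <- function(object, ...) {
  d <- canvas_coordinates(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$azimuth, .data$elevation,
                                  fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)", fill = "luminance") +
    ggplot2::theme_minimal()
}

#' Plot a rendered image
#' @param object An `rw_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rw_image <- function(object, ...) {
  m <- unclass(object)
  d <- tibble::tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(rev(seq_len(nrow(m))), times = ncol(m)),
    luminance = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "pixel", y = "pixel", fill = "luminance") +
    ggplot2::theme_void()
}

#' Plot a receptive-field map
#' @param object An `rf_map` from [compute_rf()].
#' @param ... Unused.
#' @return A ggplot heat map (grid row 1 at the top, matching the
#'   stimulus layout).
#' @exportS3Method ggplot2::autoplot
autoplot.rf_map <- function(object, ...) {
  d <- generics::tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$response)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row",
                  fill = "response\n(spikes/s)") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed firing-rate trace
#' @param object A `rate_trace` from [bin_and_smooth_rate()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_s, .data$rate_hz)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "rate (spikes/s)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted gamma curve
#' @param object A `gamma_model` from [fit_gamma()].
#' @param ... Unused.
#' @return A ggplot of luminance against command value.
#' @export
autoplot.gamma_model <- function(object, ...) {
  v <- seq(0, 1, length.out = 101)
  d <- tibble::tibble(command = v, luminance = predict(object, v))
  ggplot2::ggplot(d, ggplot2::aes(.data$command, .data$luminance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "command value", y = "luminance (cd/m²)") +
    ggplot2::theme_minimal()
}
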