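#' Plot the DMD eigenvalue spectrum on the unit circle
#'
#' Eigenvalues inside the unit circle decay; phase encodes oscillation
#' frequency per year.
#'
#' @param object a fitted `dmd`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dmd <- function(object, ...) {
  spec <- eigen_spectrum(object)
  theta <- seq(0, 2 * pi, length.out = 361)
  circle <- tibble::tibble(x = cos(theta), y = sin(theta))
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_path(data = circle, ggplot2::aes(x = .data$x, y = .data$y),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$inside_unit_circle), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re(λ)", y = "Im(λ)", colour = "decaying",
                  title = "DMD eigenvalue spectrum") +
    ggplot2::theme_minimal()
}

#' Plot forecast error and retained energy across truncation ranks
#'
#' @param object a [rank_sweep()] result.
#' @param ... unused.
#' @return a ggplot faceted into the RMSE and energy-ratio curves.
#' @export
autoplot.dmd_rank_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("rmse", "energy_ratio"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "truncation rank r", y = NULL,
                  title = "Holdout RMSE and SVD energy ratio by rank") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-actual overlay for every model
#'
#' @param forecasts a [forecast_all()] result with an `actual` column.
#' @param sort_by_actual order counties by actual rate (default `TRUE`).
#' @return a ggplot, one facet per model.
#' @export
plot_comparison <- function(forecasts, sort_by_actual = TRUE) {
  long <- comparison_table(forecasts, sort_by_actual = sort_by_actual)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$county_index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$actual), colour = "red",
                        size = 0.4, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted), colour = "blue",
                        size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "county (ordered)", y = "rate per 100,000",
                  title = "Predicted (blue) vs actual (red) rates") +
    ggplot2::theme_minimal()
}
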