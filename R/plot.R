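# Uptake trend figure: observed yearly uptake with the fitted linear trend
# and its projection.

#' Plot uptake trends with projections
#'
#' Observed yearly uptake (points and solid line) with the closed-form
#' linear fit (dashed) extended to a projection horizon, for total-product
#' and eligible-product uptake.
#'
#' @param series Output of [uptake_series()] (overall, no stratum).
#' @param horizon_year Projection horizon; `NULL` plots only the fit
#'   window.
#' @return A ggplot object.
#' @export
plot_uptake_trend <- function(series, horizon_year = NULL) {
  long <- series |>
    tidyr::pivot_longer(c("uptake_total", "uptake_eligible"),
                        names_to = "measure", values_to = "uptake") |>
    dplyr::mutate(measure = ifelse(.data$measure == "uptake_total",
                                   "per total products", "per eligible products"))
  fits <- lapply(split(long, long$measure), function(d) {
    fit <- fit_linear_trend(d$year, d$uptake)
    proj <- project_uptake(fit, horizon_year %||% max(d$year), from_year = min(d$year))
    proj$measure <- d$measure[1]
    proj
  })
  proj <- dplyr::bind_rows(fits)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$uptake,
                                     colour = .data$measure)) +
    ggplot2::geom_line(data = proj,
                       ggplot2::aes(y = .data$clamped), linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "launch year", y = "uptake", colour = NULL) +
    ggplot2::theme_minimal()
}
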