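# Uptake statistics: proportions, closed-form linear trend with t-based
# slope CI and projections, chi-square comparisons, and stratified reports.

#' Round half-up
#'
#' Report percentages use commercial rounding (half away from zero), not
#' banker's rounding, to match published display conventions.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Uptake proportions
#'
#' `uptake_total()` is labeled products over all newly launched products;
#' `uptake_eligible()` is labeled products over eligible products. Both
#' return the exact ratio (NA when the denominator is zero); display
#' formatting is a separate concern ([format_pct()]).
#'
#' @param n_labeled,n_total,n_eligible Non-negative counts.
#' @return Proportion in \[0, 1\], NA if the denominator is 0.
#' @examples
#' uptake_total(829, 7767)    # 0.1067...
#' uptake_eligible(829, 2097) # 0.3953...
#' @export
uptake_total <- function(n_labeled, n_total) {
  stopifnot(all(n_labeled >= 0, na.rm = TRUE), all(n_labeled <= n_total, na.rm = TRUE))
  ifelse(n_total > 0, n_labeled / n_total, NA_real_)
}

#' @rdname uptake_total
#' @export
uptake_eligible <- function(n_labeled, n_eligible) {
  stopifnot(all(n_labeled >= 0, na.rm = TRUE), all(n_labeled <= n_eligible, na.rm = TRUE))
  ifelse(n_eligible > 0, n_labeled / n_eligible, NA_real_)
}

#' Format a proportion as a one-decimal percentage
#'
#' @param p Proportion in \[0, 1\] (NA allowed).
#' @return Character, e.g. `"39.5"`; `"N/A"` for NA.
#' @export
format_pct <- function(p) {
  ifelse(is.na(p), "N/A", sprintf("%.1f", round_half_up(100 * p, 1)))
}

#' Yearly uptake series for a batch
#'
#' Counts labeled, eligible and total products per release year, restricted
#' to in-scope, in-window records, optionally within one stratum.
#'
#' @param batch An annotated batch (after [check_eligibility_batch()]).
#' @param by Optional stratum column name (e.g. `"reporting_group"`,
#'   `"hsr_stars"`, `"manufacturer"`); `NULL` for the overall series.
#' @return A tibble with `year`, `n_labeled`, `n_eligible`, `n_total`,
#'   `uptake_total`, `uptake_eligible` (and the stratum column when `by`
#'   is given).
#' @export
uptake_series <- function(batch, by = NULL) {
  dat <- dplyr::filter(batch, .data$in_scheme_scope & .data$in_window)
  keys <- c(by, "year")
  dat$year <- dat$release_year
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_labeled = sum(.data$thcl_displayed & .data$eligible),
      n_eligible = sum(.data$eligible),
      n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(uptake_total = uptake_total(.data$n_labeled, .data$n_total),
                  uptake_eligible = uptake_eligible(.data$n_labeled, .data$n_eligible))
  tibble::as_tibble(out)
}

#' Closed-form linear trend fit
#'
#' Least squares of proportion on period index by the closed-form normal
#' equations: `b = (n * sum(ty) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)`
#' and `a = (sum(y) - b * sum(t)) / n`. Years are encoded as X = 1, 2, ...
#' from the first fit year. The slope 95% CI uses the OLS standard error
#' with a t quantile at n - 2 degrees of freedom; R-squared is
#' `1 - SSres/SStot` (NA for a constant series, reported as degenerate).
#'
#' @param years Integer vector of calendar years (>= 2 distinct).
#' @param y Proportions, same length.
#' @param conf_level CI level for the slope.
#' @return A `fopnl_trend` list: `intercept`, `slope`, `r_squared`,
#'   `slope_ci` (length-2), `fit_window`, `x_origin` (calendar year at
#'   X = 1), `degenerate`.
#' @examples
#' fit_linear_trend(2017:2021, 0.05 + 0.03 * (1:5))
#' @export
fit_linear_trend <- function(years, y, conf_level = 0.95) {
  keep <- !is.na(y)
  years <- years[keep]; y <- y[keep]
  n <- length(y)
  if (n < 2 || length(unique(years)) < 2) stop("trend fit needs >= 2 distinct years")
  o <- order(years); years <- years[o]; y <- y[o]
  t <- years - min(years) + 1
  b <- (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
  a <- (sum(y) - b * sum(t)) / n
  res <- y - (a + b * t)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  se_b <- if (n > 2) sqrt(ss_res / (n - 2) / sum((t - mean(t))^2)) else NA_real_
  tq <- if (n > 2) qt(1 - (1 - conf_level) / 2, df = n - 2) else NA_real_
  structure(list(intercept = a, slope = b, r_squared = r2,
                 slope_ci = c(b - tq * se_b, b + tq * se_b),
                 slope_se = se_b,
                 fit_window = range(years), x_origin = min(years),
                 degenerate = ss_tot == 0),
            class = "fopnl_trend")
}

#' @export
print.fopnl_trend <- function(x, ...) {
  cat(sprintf("<fopnl_trend> y = %.4f + %.4f X (X=1 at %d), R^2 = %s, slope 95%% CI [%.4f, %.4f]\n",
              x$intercept, x$slope, x$x_origin,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Project an uptake trend forward
#'
#' Linear extrapolation per year up to the horizon. Displayed values are
#' clamped to \[0, 1\]; the unclamped prediction is retained alongside.
#'
#' @param fit A [fit_linear_trend()] object (or a list with `intercept`,
#'   `slope`, `x_origin`).
#' @param horizon_year Last calendar year to project (at or after the fit
#'   window end).
#' @param from_year First projected year; defaults to the fit window end.
#' @return Tibble with `year`, `x`, `predicted` (unclamped), `clamped`.
#' @examples
#' # published overall-uptake fit: y = 0.0301 x - 0.0199, X = 1 at 2017
#' fit <- list(intercept = -0.0199, slope = 0.0301, x_origin = 2017)
#' project_uptake(fit, 2027, from_year = 2022)
#' @export
project_uptake <- function(fit, horizon_year, from_year = NULL) {
  from_year <- from_year %||% (fit$fit_window %||% c(NA, fit$x_origin))[2]
  stopifnot(horizon_year >= from_year)
  years <- seq(from_year, horizon_year)
  x <- years - fit$x_origin + 1
  pred <- fit$intercept + fit$slope * x
  tibble::tibble(year = years, x = x, predicted = pred,
                 clamped = pmin(1, pmax(0, pred)))
}

#' Chi-square comparison of uptake across strata
#'
#' Pearson chi-square without continuity correction on the 2 x k table of
#' labeled vs not-labeled counts by stratum, df = k - 1. A warning
#' annotation (not an error) is attached when any expected cell is below 1.
#'
#' @param labeled,total Integer vectors per stratum (`total >= labeled`).
#' @return List: `statistic`, `df`, `p_value`, `expected`, `warning`.
#' @export
chi_square_uptake <- function(labeled, total) {
  stopifnot(length(labeled) == length(total), all(total > 0),
            all(labeled >= 0), all(labeled <= total))
  obs <- rbind(labeled, total - labeled)
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - e)^2 / e)
  df <- ncol(obs) - 1
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE),
       expected = e, warning = if (any(e < 1)) "expected cell < 1" else NULL)
}

#' Stratified uptake report
#'
#' One row per stratum with labeled/total, labeled/eligible and
#' eligible/total counts, one-decimal percentages, and the per-stratum
#' linear trend (slope in percentage points per annum, R-squared).
#' Manufacturer reports list individually only makers with at least
#' `min_labeled` labeled products and fold the rest into
#' `"All other companies"`.
#'
#' @param batch An annotated batch (after [check_eligibility_batch()]; an
#'   `hsr_stars` column is required for `by = "hsr_stars"`).
#' @param by Stratum column: `"reporting_group"`, `"hsr_stars"`,
#'   `"manufacturer"`, or `NULL` for a single overall row.
#' @param min_labeled Individual-listing threshold for manufacturers.
#' @return A tibble report; the overall `Total` row is appended last.
#' @export
build_report <- function(batch, by = "reporting_group", min_labeled = 5) {
  dat <- dplyr::filter(batch, .data$in_scheme_scope & .data$in_window)
  if (identical(by, "manufacturer")) {
    lab_by_maker <- dat |>
      dplyr::group_by(.data$manufacturer) |>
      dplyr::summarise(nl = sum(.data$thcl_displayed & .data$eligible), .groups = "drop")
    keep <- lab_by_maker$manufacturer[lab_by_maker$nl >= min_labeled]
    dat$stratum <- ifelse(dat$manufacturer %in% keep, dat$manufacturer,
                          "All other companies")
  } else if (is.null(by)) {
    dat$stratum <- "Total"
  } else {
    dat$stratum <- as.character(dat[[by]])
  }

  one_row <- function(d, label) {
    nl <- sum(d$thcl_displayed & d$eligible)
    ne <- sum(d$eligible)
    nt <- nrow(d)
    ser <- uptake_series(d)
    tr_t <- tryCatch(fit_linear_trend(ser$year, ser$uptake_total),
                     error = function(e) NULL)
    tr_e <- tryCatch(fit_linear_trend(ser$year, ser$uptake_eligible),
                     error = function(e) NULL)
    tibble::tibble(
      stratum = label,
      n_labeled = nl, n_eligible = ne, n_total = nt,
      labeled_total = sprintf("%d/%d", nl, nt),
      labeled_total_pct = format_pct(uptake_total(nl, nt)),
      labeled_eligible = sprintf("%d/%d", nl, ne),
      labeled_eligible_pct = format_pct(uptake_eligible(nl, ne)),
      eligible_total = sprintf("%d/%d", ne, nt),
      eligible_total_pct = format_pct(uptake_total(ne, nt)),
      trend_total_slope_pct = if (is.null(tr_t)) NA_real_ else 100 * tr_t$slope,
      trend_total_r2 = if (is.null(tr_t)) NA_real_ else tr_t$r_squared,
      trend_eligible_slope_pct = if (is.null(tr_e)) NA_real_ else 100 * tr_e$slope,
      trend_eligible_r2 = if (is.null(tr_e)) NA_real_ else tr_e$r_squared
    )
  }

  strata <- sort(unique(dat$stratum))
  rows <- purrr::map_dfr(strata, function(s) one_row(dat[dat$stratum == s, ], s))
  dplyr::bind_rows(rows, one_row(dat, "Total"))
}

#' Published uptake counts fixture
#'
#' The reported labeled/eligible/total count pairs of the five-year Thai
#' surveillance (overall, by the 18 reporting groups, by manufacturer, and
#' by healthfulness band), shipped as a plain-text asset. Used as
#' arithmetic-check input and as calibration targets for
#' [default_study_scenario()]. Two cells whose printed percentages
#' disagree with their own counts are flagged `discrepant`.
#'
#' @return Tibble with `source`, `stratum`, `ratio`, `n`, `N`,
#'   `printed_pct`, `discrepant`.
#' @export
reported_uptake <- function() {
  readr::read_csv(fopnl_asset("thcl_reported_uptake.csv"),
                  show_col_types = FALSE, progress = FALSE)
}
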