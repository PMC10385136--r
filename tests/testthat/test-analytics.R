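test_that("uptake ratios reproduce the headline proportions", {
  expect_equal(format_pct(uptake_total(829, 7767)), "10.7")
  expect_equal(format_pct(uptake_eligible(829, 2097)), "39.5")
  expect_equal(format_pct(uptake_total(64, 266)), "24.1")
  expect_equal(format_pct(uptake_eligible(125, 195)), "64.1")
  expect_equal(format_pct(uptake_total(0, 50)), "0.0")
  expect_equal(format_pct(uptake_eligible(7, 7)), "100.0")
  expect_equal(format_pct(uptake_eligible(0, 0)), "N/A")
  expect_true(is.na(uptake_total(0, 0)))
  expect_error(uptake_total(5, 3))
})

test_that("percent formatting rounds half up and round-trips", {
  expect_equal(round_half_up(28.125, 1), 28.1)
  expect_equal(round_half_up(6.25, 1), 6.3)      # half-up, not banker's
  expect_equal(round_half_up(-6.25, 1), -6.3)
  p <- runif(100)
  reparsed <- as.numeric(format_pct(p)) / 100
  expect_true(all(abs(reparsed - p) <= 0.0005 + 1e-12))
})

test_that("the closed-form trend fit equals the least-squares oracle", {
  set.seed(42)
  for (r in 1:50) {
    n <- sample(3:8, 1)
    years <- sort(sample(2010:2030, n))
    y <- runif(n)
    fit <- fit_linear_trend(years, y)
    x <- years - min(years) + 1
    ref <- lm(y ~ x)
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
    expect_equal(unname(fit$slope_ci), unname(confint(ref)["x", ]), tolerance = 1e-8)
  }
})

test_that("exact lines and degenerate series are fitted faithfully", {
  fit <- fit_linear_trend(2017:2021, 0.05 + 0.03 * (1:5))
  expect_equal(fit$slope, 0.03, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  const <- fit_linear_trend(2017:2021, rep(0.2, 5))
  expect_equal(const$slope, 0)
  expect_true(const$degenerate)
  expect_true(is.na(const$r_squared))
  expect_error(fit_linear_trend(2020, 0.1), "2 distinct years")
})

test_that("projections extrapolate linearly and clamp for display", {
  fit <- list(intercept = 0.05, slope = 0.03, x_origin = 2017,
              fit_window = c(2017, 2021))
  proj <- project_uptake(fit, 2027)
  expect_equal(proj$predicted, 0.05 + 0.03 * (5:11))
  flat <- list(intercept = 0.2, slope = 0, x_origin = 2017, fit_window = c(2017, 2021))
  expect_true(all(project_uptake(flat, 2027)$predicted == 0.2))
  steep <- list(intercept = 0, slope = 0.2, x_origin = 2017, fit_window = c(2017, 2021))
  p <- project_uptake(steep, 2027)
  expect_true(any(p$predicted > 1))
  expect_true(all(p$clamped <= 1))
})

test_that("chi-square matches the O/E oracle and its scale property", {
  ref <- function(labeled, total) {
    obs <- rbind(labeled, total - labeled)
    suppressWarnings(stats::chisq.test(t(obs), correct = FALSE))
  }
  res <- chi_square_uptake(c(20, 35), c(100, 100))
  oracle <- ref(c(20, 35), c(100, 100))
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, unname(oracle$p.value), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # identical proportions -> zero statistic, p = 1
  same <- chi_square_uptake(c(10, 20), c(50, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # doubling all cells doubles the statistic
  x2 <- chi_square_uptake(c(40, 70), c(200, 200))
  expect_equal(x2$statistic, 2 * res$statistic, tolerance = 1e-12)
  # small expected cells annotate a warning
  expect_equal(chi_square_uptake(c(0, 1), c(2, 400))$warning, "expected cell < 1")
})

test_that("stratified reports are marginally consistent and fold small makers", {
  sc <- small_scenario(scale = 0.2)
  ann <- annotate_batch(generate_products(sc, seed = 9))
  rep_cat <- build_report(ann, by = "reporting_group")
  tot <- rep_cat[rep_cat$stratum == "Total", ]
  strata <- rep_cat[rep_cat$stratum != "Total", ]
  expect_equal(sum(strata$n_labeled), tot$n_labeled)
  expect_equal(sum(strata$n_eligible), tot$n_eligible)
  expect_equal(sum(strata$n_total), tot$n_total)
  # percentages in the report equal 100 * n/N rounded half-up
  expect_equal(rep_cat$labeled_total_pct,
               format_pct(rep_cat$n_labeled / rep_cat$n_total))

  rep_man <- build_report(ann, by = "manufacturer", min_labeled = 5)
  listed <- setdiff(rep_man$stratum, c("All other companies", "Total"))
  expect_true(all(rep_man$n_labeled[rep_man$stratum %in% listed] >= 5))
  expect_true("All other companies" %in% rep_man$stratum)

  # a stratum with no eligible products reports N/A for eligible uptake
  none <- ann[ann$reporting_group == "small meals", ]
  expect_true(all(build_report(none, by = NULL)$labeled_eligible_pct %in%
                    c("N/A", "0.0")))
})

test_that("hand-built counts give the hand-computed report row", {
  n <- 40
  b <- record_batch(tibble::tibble(
    barcode = paste0("H", 1:n),
    release_year = rep(2017:2021, each = 8),
    manufacturer = "m",
    gnpd_minor = "carbonated_soft_drinks",
    thcl_displayed = rep(c(TRUE, FALSE, FALSE, FALSE), 10),
    sugar_g = rep(c(2, 4, 5, 9), 10),   # 3 of 4 eligible per quartet
    sodium_mg = 10, sat_fat_g = 0, basis = "per100mL"))
  ann <- check_eligibility_batch(assign_category(b))
  row <- build_report(ann, by = NULL)[1, ]
  expect_equal(row$labeled_total, "10/40")
  expect_equal(row$labeled_total_pct, "25.0")
  expect_equal(row$labeled_eligible, "10/30")
  expect_equal(row$labeled_eligible_pct, "33.3")
  expect_equal(row$eligible_total_pct, "75.0")
})
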