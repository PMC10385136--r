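tables <- read_hsr_tables()

test_that("band lookups are closed on the lower edge and saturate on top", {
  zero <- tibble::tibble(energy_kj = 0, sat_fat_g = 0, sugar_g = 0, sodium_mg = 0,
                         protein_g = 0, fiber_g = 0,
                         fvnl_nonconc_pct = 0, fvnl_conc_pct = 0)
  expect_equal(baseline_points(zero, tables, "2"), 0L)
  # a value exactly on a band edge earns that band's points
  on_edge <- zero; on_edge$energy_kj <- 335
  expect_equal(baseline_points(on_edge, tables, "2"), 1L)
  below <- zero; below$energy_kj <- 334.999
  expect_equal(baseline_points(below, tables, "2"), 0L)
  # beyond the top band the points saturate
  extreme <- zero; extreme$sodium_mg <- 1e6
  expect_equal(baseline_points(extreme, tables, "2"),
               length(tables$baseline$sodium_mg))
  # beverages use the finer energy bands
  bev <- zero; bev$energy_kj <- 180
  expect_equal(baseline_points(bev, tables, "1"), 2L)
  expect_equal(baseline_points(bev, tables, "2"), 0L)
})

test_that("a mid-range food panel scores as the hand lookup says", {
  # manual table walk: energy 1005 kJ -> 3; sat fat 2.5 g -> 2;
  # sugar 13.4 g -> 3; sodium 450 mg -> 5 => baseline 13.
  # FVNL 50% -> 2 V; protein 5 g -> 3 P but capped (baseline >= 13, V < 5);
  # fiber 2.0 g -> 2 F => score 13 - 4 = 9 -> 2.5 stars in the food matrix.
  p <- tibble::tibble(energy_kj = 1005, sat_fat_g = 2.5, sugar_g = 13.4,
                      sodium_mg = 450, protein_g = 5, fiber_g = 2.0,
                      fvnl_nonconc_pct = 50, fvnl_conc_pct = 0)
  base <- baseline_points(p, tables, "2")
  expect_equal(base, 13L)
  mods <- modifying_points(p, tables, base, "2")
  expect_equal(mods, tibble::tibble(v = 2L, p = 0L, f = 2L))
  expect_equal(score_to_stars(base - sum(mods), "2", tables), 2.5)
})

test_that("modifying points follow FVNL, protein and fiber content", {
  none <- tibble::tibble(protein_g = 0, fiber_g = 0,
                         fvnl_nonconc_pct = 0, fvnl_conc_pct = 0)
  expect_equal(modifying_points(none, tables, 0L, "2"),
               tibble::tibble(v = 0L, p = 0L, f = 0L))
  # sole-ingredient juice reaches the maximal V band
  juice <- tibble::tibble(protein_g = 0.5, fiber_g = 0.2,
                          fvnl_nonconc_pct = 100, fvnl_conc_pct = 100)
  expect_equal(modifying_points(juice, tables, 0L, "1")$v,
               length(tables$modifying$fvnl_pct))
  # concentrated-only content still reaches 100% through the weighting
  expect_equal(combined_fvnl_pct(0, 100, tables), 100)
  expect_equal(combined_fvnl_pct(40, 0, tables), 40)
  # protein cap: high baseline with low V forces P to zero,
  # enough V releases it
  rich <- tibble::tibble(protein_g = 10, fiber_g = 0,
                         fvnl_nonconc_pct = 0, fvnl_conc_pct = 0)
  expect_equal(modifying_points(rich, tables, 20L, "2")$p, 0L)
  expect_gt(modifying_points(rich, tables, 5L, "2")$p, 0L)
  rich_v <- rich; rich_v$fvnl_nonconc_pct <- 90
  expect_gt(modifying_points(rich_v, tables, 20L, "2")$p, 0L)
})

test_that("the star matrices cover both extremes and half-star steps only", {
  expect_equal(score_to_stars(-1000L, "2", tables), 5.0)
  expect_equal(score_to_stars(1000L, "2", tables), 0.5)
  stars <- score_to_stars(seq(-30L, 40L), "2D", tables)
  expect_true(all(stars %in% seq(0.5, 5, by = 0.5)))
  expect_true(all(diff(stars) <= 0))  # monotone non-increasing in score
})

test_that("star grades collapse to the five-letter scale", {
  expect_equal(hsr_to_grade(5.0, tables), "A")
  expect_equal(hsr_to_grade(3.5, tables), "B")
  expect_equal(hsr_to_grade(0.5, tables), "E")
  expect_equal(hsr_to_grade(c(4.5, 2.0, 1.5), tables), c("A", "C", "D"))
})

test_that("HSR category routing uses hints first, basis fallback second", {
  expect_equal(assign_hsr_category("1D", "per100mL"), "1D")
  expect_equal(assign_hsr_category(NA, "per100mL"), "1")
  expect_equal(assign_hsr_category(NA, "per100g", dairy = TRUE), "2D")
  expect_error(assign_hsr_category("9", "per100g"), "unknown HSR category")
})

test_that("scored batches satisfy the score identity and determinism", {
  sc <- small_scenario()
  ann <- annotate_batch(generate_products(sc, seed = 5))
  scored <- ann[ann$hsr_scored, ]
  expect_gt(nrow(scored), 100)
  expect_identical(scored$hsr_score,
                   scored$hsr_baseline - (scored$hsr_v + scored$hsr_p + scored$hsr_f))
  expect_true(all(scored$hsr_stars %in% seq(0.5, 5, by = 0.5)))
  ann2 <- annotate_batch(generate_products(sc, seed = 5))
  expect_identical(ann$hsr_stars, ann2$hsr_stars)
})

test_that("unscored categories yield explicit unscored results", {
  b <- record_batch(tibble::tibble(
    barcode = "C", release_year = 2019L, gnpd_minor = "cheese_like",
    thcl_displayed = FALSE, basis = "per100g", energy_kj = 1500,
    sat_fat_g = 20, sugar_g = 1, sodium_mg = 700))
  b$subgroup <- "cheese_like"; b$hsr_category <- "unscored"
  b$in_scheme_scope <- TRUE; b$in_window <- TRUE
  out <- score_hsr(b, tables)
  expect_false(out$hsr_scored)
  expect_true(is.na(out$hsr_stars))
})
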