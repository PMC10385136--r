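test_that("ingredient scanning flags fiber and FVNL sources", {
  f <- detect_fvnl_ingredients(c("water", "inulin", "sugar"))
  expect_equal(f$position[f$fiber_source], 2L)
  expect_false(any(f$fvnl_source))

  f <- detect_fvnl_ingredients(c("apple juice concentrate"))
  expect_true(f$fvnl_source)
  expect_true(f$fvnl_concentrated)

  f <- detect_fvnl_ingredients(c("water", "sugar"))
  expect_false(any(f$fiber_source | f$fvnl_source))

  expect_warning(f0 <- detect_fvnl_ingredients(character(0)), "empty")
  expect_equal(nrow(f0), 0)
})

test_that("the four FVNL allocation rules reproduce the worked cases", {
  a <- allocate_fvnl(c("orange juice"))
  expect_equal(a$conc_band, "eq100")
  expect_equal(a$assigned_conc_pct, 100)
  expect_equal(a$assigned_nonconc_pct, 100)

  a <- allocate_fvnl(c("mango puree", "citric acid"))
  expect_equal(a$conc_band, "ge67")
  expect_equal(a$nonconc_band, "gt80")

  a <- allocate_fvnl(c("water", "sugar", "carrot juice"))
  expect_equal(a$conc_band, "ge25")   # third ingredient
  expect_equal(a$nonconc_band, "le40") # but not within the first two

  a <- allocate_fvnl(c("water", "sugar", "salt", "apple"))
  expect_equal(a$conc_band, "lt25")
  expect_equal(a$nonconc_band, "le40")

  # midpoint representative stays inside the band
  m <- allocate_fvnl(c("water", "sugar", "carrot juice"), band_value = "midpoint")
  expect_gte(m$assigned_conc_pct, 25)
  expect_lte(m$assigned_nonconc_pct, 40)
})

test_that("exactly one allocation rule fires for every flag configuration", {
  band_lut <- list(eq100 = c(100, 100), ge67 = c(67, 100), gt80 = c(80, 100),
                   ge25 = c(25, 67), gt40 = c(40, 80), lt25 = c(0, 25),
                   le40 = c(0, 40))
  for (len in 1:5) {
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), 2 * len))
    for (r in seq_len(nrow(combos))) {
      fvnl <- unlist(combos[r, 1:len])
      minor <- unlist(combos[r, (len + 1):(2 * len)]) & !fvnl
      flags <- tibble::tibble(
        ingredient = paste0("i", seq_len(len)), position = seq_len(len),
        fiber_source = FALSE, fvnl_source = fvnl,
        fvnl_concentrated = FALSE, minor_additive = minor)
      a <- allocate_fvnl(flags)
      expect_equal(nrow(a), 1)
      expect_true(a$rule %in% c("sole-ingredient", "first-ingredient-minor-rest",
                                "top-ranked", "default-low"))
      # assigned value lies inside its band
      expect_gte(a$assigned_conc_pct, band_lut[[a$conc_band]][1])
      expect_lte(a$assigned_conc_pct, band_lut[[a$conc_band]][2])
      expect_gte(a$assigned_nonconc_pct, band_lut[[a$nonconc_band]][1])
      expect_lte(a$assigned_nonconc_pct, band_lut[[a$nonconc_band]][2])
    }
  }
})

make_fiber_batch <- function(fibers, energies, barcodes = NULL,
                             subgroup_minor = "potato_chips") {
  n <- length(fibers)
  if (is.null(barcodes)) barcodes <- paste0("F", seq_len(n))
  record_batch(tibble::tibble(
    barcode = barcodes,
    release_year = 2019L, gnpd_minor = subgroup_minor, thcl_displayed = FALSE,
    ingredients = rep(list(c("potato", "inulin", "salt")), n),
    energy_kj = energies, fiber_g = fibers))
}

test_that("homogeneous subgroups impute the non-zero category mean", {
  b <- assign_category(make_fiber_batch(c(2, 4, 0, NA), c(400, 500, 450, 480)))
  out <- impute_fiber(b)   # potato_chips is on the homogeneous list
  expect_equal(out$fiber_g[4], 3)               # zero donor excluded
  expect_equal(out$fiber_strategy[4], "category_mean")
  expect_equal(out$fiber_g[1:3], c(2, 4, 0))    # declared values untouched
  expect_equal(out$fiber_strategy[1:3], rep("declared", 3))
  # permutation of donor order changes nothing
  b2 <- assign_category(make_fiber_batch(c(4, 0, 2, NA), c(500, 450, 400, 480)))
  expect_equal(impute_fiber(b2)$fiber_g[4], 3)
})

test_that("heterogeneous subgroups match the nearest-energy donor", {
  b <- assign_category(make_fiber_batch(c(1.0, 7.5, NA), c(400, 900, 850),
                                        subgroup_minor = "sweet_biscuits"))
  out <- impute_fiber(b)
  expect_equal(out$fiber_g[3], 7.5)             # 900 kJ donor beats 400 kJ
  expect_equal(out$fiber_strategy[3], "matched_product")
  # energy tie broken by lower barcode
  tie <- assign_category(make_fiber_batch(c(1.0, 7.5, NA), c(800, 900, 850),
                                          barcodes = c("A2", "A1", "A3"),
                                          subgroup_minor = "sweet_biscuits"))
  expect_equal(impute_fiber(tie)$fiber_g[3], 7.5)  # donor A1 wins the tie
})

test_that("fiber imputation degrades gracefully and never invents sources", {
  # no fiber-source ingredient -> 0
  b <- record_batch(tibble::tibble(
    barcode = "P", release_year = 2019L, gnpd_minor = "carbonated_soft_drinks",
    thcl_displayed = FALSE, ingredients = list(c("water", "sugar"))))
  out <- impute_fiber(assign_category(b))
  expect_equal(out$fiber_g, 0)
  expect_equal(out$fiber_strategy, "zero")
  # fiber source but no donors -> 0 with a warning
  b2 <- assign_category(make_fiber_batch(NA_real_, 500))
  expect_warning(out2 <- impute_fiber(b2), "no fiber donors")
  expect_equal(out2$fiber_g, 0)
  # imputation never returns negatives or changes declared values
  sc <- small_scenario()
  g <- impute_fiber(assign_category(generate_products(sc, seed = 3)))
  expect_true(all(g$fiber_g >= 0))
  declared <- !is.na(generate_products(sc, seed = 3)$fiber_g)
  expect_true(all(g$fiber_strategy[declared] == "declared"))
})
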