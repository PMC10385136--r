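# Shared fixtures: a tiny hand-built batch and random standardized panels.

tiny_batch <- function() {
  record_batch(tibble::tibble(
    barcode = c("B1", "B2", "B3", "B4"),
    release_year = c(2017L, 2018L, 2019L, 2020L),
    manufacturer = c("m1", "m1", "m2", "m3"),
    gnpd_minor = c("carbonated_soft_drinks", "rtd_tea", "bread_products",
                   "drinking_water"),
    gnpd_major = c("carbonated_soft_drinks", "hot_beverages", "bakery", "water"),
    ingredients = list(c("carbonated water", "sugar", "flavouring"),
                       c("water", "tea extract", "sugar"),
                       c("wheat flour", "water", "salt"),
                       c("water")),
    thcl_displayed = c(TRUE, FALSE, FALSE, FALSE),
    basis = c("per100mL", "per100mL", "per100g", "per100mL"),
    serving_size = c(200, 200, 50, 200),
    energy_kj = c(180, 90, 1000, 0),
    total_fat_g = c(0, 0, 3, 0),
    sat_fat_g = c(0, 0, 1, 0),
    protein_g = c(0, 0.5, 8, 0),
    carb_g = c(11, 5, 48, 0),
    sugar_g = c(10.5, 4.0, 4, 0),
    fiber_g = c(0, 0, 2.5, 0),
    sodium_mg = c(15, 10, 400, 2)
  ), provenance = "test fixture")
}

# random but panel-invariant-respecting standardized panels for property tests
random_panels <- function(n, seed = 1) {
  set.seed(seed)
  fat <- rlnorm(n, log(4), 0.8)
  sugar <- rlnorm(n, log(8), 0.9)
  tibble::tibble(
    basis = sample(c("per100g", "per100mL"), n, replace = TRUE),
    serving_size = sample(c(30, 50, 100, 200), n, replace = TRUE),
    energy_kj = rlnorm(n, log(800), 0.9),
    total_fat_g = fat,
    sat_fat_g = fat * runif(n, 0, 1),
    protein_g = rlnorm(n, log(4), 0.8),
    sugar_g = sugar,
    carb_g = sugar + rlnorm(n, log(10), 0.7),
    fiber_g = rlnorm(n, log(1.5), 0.8),
    sodium_mg = rlnorm(n, log(250), 1.1),
    fvnl_nonconc_pct = runif(n, 0, 100),
    fvnl_conc_pct = runif(n, 0, 100)
  )
}

small_scenario <- function(scale = 0.1, ...) {
  default_study_scenario(scale = scale, ...)
}
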