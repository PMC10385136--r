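# Synthetic launch-database generator.
#
# Emulates a commercial new-product database: one row per barcode, a
# category code drawn from the crosswalk, a subgroup-consistent nutrient
# panel, an ordered ingredient list consistent with the product's FVNL and
# fiber draws, a manufacturer from a few-large/many-small firm model, and a
# logo-display flag drawn conditional on true eligibility with a
# year-dependent display curve. Ground-truth annotations ride along so
# every pipeline stage can be checked against a closed loop.

# per-subgroup ingredient templates; names chosen so the lexicon scan
# reproduces the intended FVNL band (closed loop with allocate_fvnl)
.ingredient_templates <- list(
  cakes = c("wheat flour", "sugar", "egg", "palm oil", "baking powder"),
  cookies_biscuits = c("wheat flour", "sugar", "palm oil", "salt"),
  sliced_bread = c("wheat flour", "water", "yeast", "salt", "whole wheat flour"),
  breakfast_cereal = c("whole grain oats", "sugar", "salt"),
  white_milk = c("cow's milk"),
  flavored_milk = c("cow's milk", "sugar", "cocoa"),
  yogurt = c("cow's milk", "sugar", "milk culture"),
  dressing = c("water", "palm oil", "sugar", "salt"),
  mayonnaise = c("palm oil", "egg yolk", "salt"),
  ice_cream = c("cow's milk", "sugar", "cream", "stabilizer"),
  instant_noodles = c("wheat flour", "palm oil", "salt", "seasoning"),
  instant_porridge = c("rice", "salt", "dried chicken"),
  instant_tea = c("water", "tea extract", "sugar"),
  instant_coffee = c("water", "coffee extract", "sugar"),
  malt_chocolate_drink = c("cow's milk", "malt extract", "sugar", "cocoa"),
  soy_milk = c("water", "soybean", "sugar"),
  nut_cereal_milk = c("water", "almond", "sugar"),
  frozen_meal = c("rice", "chicken", "palm oil", "salt"),
  chilled_meal = c("rice", "pork", "palm oil", "salt"),
  fish_sauce = c("anchovy extract", "salt", "sugar"),
  soy_sauce = c("soybean", "wheat", "salt"),
  seasoning_powder = c("salt", "sugar", "monosodium glutamate"),
  small_meal = c("wheat flour", "pork", "palm oil"),
  potato_chips = c("potato", "palm oil", "salt"),
  extruded_snack = c("rice flour", "palm oil", "salt"),
  meat_snack = c("pork", "sugar", "salt"),
  nuts_seeds = c("peanut", "salt"),
  bean_snack = c("mung bean", "salt", "flavouring"),
  wet_soup = c("water", "chicken", "salt"),
  instant_soup = c("corn starch", "salt", "dried shrimp"),
  carbonated_soft_drink = c("carbonated water", "sugar", "flavouring"),
  functional_drink = c("water", "sugar", "taurine", "flavouring"),
  fruit_juice = c("orange juice"),
  vegetable_juice = c("carrot juice"),
  juice_drink = c("water", "sugar", "orange juice")
)

.default_serving <- function(subgroup, basis) {
  ifelse(subgroup %in% c("instant_noodles", "instant_porridge", "instant_soup"), 50,
         ifelse(basis == "per100mL", 200, 100))
}

#' Default study scenario
#'
#' A shipped generator configuration whose expected aggregate moments echo
#' the five-year Thai surveillance: about 27% of launches eligible, 10.7%
#' labeled overall, 39.5% labeled among eligible, category mix proportional
#' to the published per-group launch counts, per-group criteria start years
#' from the category map, and per-group linear-in-year display curves with
#' a pooled eligible-uptake slope near 0.10 per annum. These are
#' calibration targets for a synthetic stand-in, not claims of equivalence
#' to any proprietary database.
#'
#' Calibration works backwards from the published counts: each subgroup's
#' binding (first) criteria condition gets a log-normal nutrient
#' distribution whose mass below the threshold equals the group's observed
#' eligible share, and each group's display curve is centred on its
#' observed eligible-uptake with global slope 0.1024 per annum, shrunk per
#' group just enough to stay inside \[0, 1\].
#'
#' @param years Study years.
#' @param scale Launch-count scale factor (1 reproduces the full ~7767
#'   launches; smaller values give proportionally smaller batches for quick
#'   tests).
#' @param display_slope Annual increase of the display-given-eligible
#'   probability.
#' @param anomaly_rate P(display | ineligible); 0 by default so labeled
#'   products are eligible by construction.
#' @param fiber_missing_p Probability that a solid food's fiber declaration
#'   is missing (exercises the imputation path).
#' @param n_firms,zipf_s Manufacturer model: number of firms and the Zipf
#'   exponent of the firm-size distribution (few large, many small firms).
#' @return A `fopnl_scenario` list with the per-cell launch counts, the
#'   per-subgroup nutrient models, the display curves, and the expected
#'   pooled eligible-uptake curve with its OLS slope (the recovery truth).
#' @export
default_study_scenario <- function(years = 2017:2021, scale = 1,
                                   display_slope = 0.1024,
                                   anomaly_rate = 0,
                                   fiber_missing_p = 0.25,
                                   n_firms = 1875, zipf_s = 1.1) {
  map <- read_category_map()
  criteria <- read_criteria()
  rep_tab <- reported_uptake() |>
    dplyr::filter(.data$source == "table1", .data$stratum != "Total")
  counts <- rep_tab |>
    tidyr::pivot_wider(id_cols = "stratum", names_from = "ratio",
                       values_from = c("n", "N")) |>
    dplyr::transmute(reporting_group = .data$stratum,
                     n_total = .data$N_labeled_total,
                     n_eligible = .data$n_eligible_total,
                     n_labeled = .data$n_labeled_total)

  sub <- dplyr::left_join(map$subgroups, counts, by = "reporting_group")
  stopifnot(!anyNA(sub$n_total))

  # launch cells: distribute each group's count over its subgroups x window
  cells <- purrr::map_dfr(
    split(sub, sub$reporting_group),
    function(g) {
      window <- seq(max(min(years), min(g$start_year)), max(years))
      grid <- tidyr::expand_grid(subgroup = g$subgroup, year = window)
      n_cells <- nrow(grid)
      total <- round(g$n_total[1] * scale)
      base <- total %/% n_cells
      extra <- total - base * n_cells
      grid$n <- base + (seq_len(n_cells) <= extra)
      grid
    })

  # per-group eligibility and display calibration
  grp <- counts |>
    dplyr::mutate(
      e = .data$n_eligible / .data$n_total,
      u = ifelse(.data$n_eligible > 0, .data$n_labeled / .data$n_eligible, 0))
  grp <- dplyr::left_join(
    grp,
    sub |> dplyr::group_by(.data$reporting_group) |>
      dplyr::summarise(start = max(min(years), min(.data$start_year))),
    by = "reporting_group")
  grp$x_mean <- (grp$start + max(years)) / 2 - min(years) + 1
  x_min <- 1
  x_max <- max(years) - min(years) + 1
  grp$slope <- pmax(0, pmin(display_slope,
                            ifelse(grp$u > 0, grp$u / pmax(grp$x_mean - (grp$start - min(years) + 1), 1e-9), 0),
                            (1 - grp$u) / pmax(x_max - grp$x_mean, 1e-9)))

  # per-subgroup nutrient models; the binding (first) condition is
  # calibrated so P(pass) equals the group's eligible share
  sdlog <- 0.5
  sub$serving_size <- .default_serving(sub$subgroup, sub$basis)
  first_cond <- criteria$conditions |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::slice(1) |> dplyr::ungroup()
  sub <- dplyr::left_join(sub, first_cond[, c("subgroup", "nutrient", "cmp", "threshold", "basis")],
                          by = "subgroup", suffix = c("", "_cond"))
  sub$t_eff <- ifelse(sub$basis_cond == "per_serving",
                      sub$threshold * 100 / sub$serving_size, sub$threshold)
  e_grp <- grp$e[match(sub$reporting_group, grp$reporting_group)]
  sub$binding_meanlog <- log(sub$t_eff) - sdlog * qnorm(pmin(pmax(e_grp, 1e-6), 1 - 1e-6))
  sub$binding_sdlog <- sdlog

  structure(list(
    years = years, scale = scale,
    subgroups = sub, groups = grp, cells = cells,
    display_slope = display_slope, anomaly_rate = anomaly_rate,
    fiber_missing_p = fiber_missing_p,
    n_firms = n_firms, zipf_s = zipf_s,
    criteria = criteria, map = map
  ), class = "fopnl_scenario")
}

#' @export
print.fopnl_scenario <- function(x, ...) {
  cat(sprintf("<fopnl_scenario> %d launches over %d-%d, %d subgroups, display slope %.4f/yr\n",
              sum(x$cells$n), min(x$years), max(x$years),
              nrow(x$subgroups), x$display_slope))
  invisible(x)
}

#' Expected uptake curves and true slope of a scenario
#'
#' Deterministic expectation of the pooled yearly eligible-uptake and
#' total-uptake proportions under the scenario's display curves and
#' eligibility calibration, plus the ordinary-least-squares slope of the
#' expected eligible-uptake series. This is the ground truth that
#' parameter-recovery runs compare against.
#'
#' @param scenario A [default_study_scenario()] object.
#' @return List: `curve` (tibble `year`, `p_display`, `n_total`,
#'   `n_eligible_exp`), `slope_eligible`, `slope_total`.
#' @export
scenario_truth <- function(scenario) {
  grp <- scenario$groups
  sub <- scenario$subgroups
  cells <- scenario$cells
  cells$reporting_group <- sub$reporting_group[match(cells$subgroup, sub$subgroup)]
  cells$e <- grp$e[match(cells$reporting_group, grp$reporting_group)]
  cells$x <- cells$year - min(scenario$years) + 1
  gi <- match(cells$reporting_group, grp$reporting_group)
  cells$p <- pmin(1, pmax(0, grp$u[gi] + grp$slope[gi] * (cells$x - grp$x_mean[gi])))
  curve <- cells |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_total = sum(.data$n),
      n_eligible_exp = sum(.data$n * .data$e),
      n_labeled_exp = sum(.data$n * .data$e * .data$p), .groups = "drop") |>
    dplyr::mutate(p_eligible_uptake = .data$n_labeled_exp / .data$n_eligible_exp,
                  p_total_uptake = .data$n_labeled_exp / .data$n_total)
  x <- curve$year - min(curve$year) + 1
  list(curve = curve,
       slope_eligible = unname(coef(lm(curve$p_eligible_uptake ~ x))[2]),
       slope_total = unname(coef(lm(curve$p_total_uptake ~ x))[2]))
}

# draw one lognormal vector per subgroup block, vectorized over rows
.rln <- function(n, meanlog, sdlog) if (n > 0) rlnorm(n, meanlog, sdlog) else numeric(0)

#' Generate a synthetic product batch
#'
#' Draws launch records per the scenario: unique barcodes, subgroup
#' category codes (mapped back to database minor codes), calibrated
#' nutrient panels per 100 basis-units, template ingredient lists
#' consistent with the FVNL/fiber draws, manufacturers from the Zipf firm
#' model, and display flags conditional on ground-truth eligibility.
#'
#' Truth columns (`true_eligible`, `true_display_p`, `true_fiber_g`)
#' are carried in the batch for oracle tests; the analysis pipeline never
#' reads them.
#'
#' @param scenario A [default_study_scenario()] object.
#' @param seed Integer seed; identical seed and scenario give an identical
#'   batch.
#' @return A `fopnl_batch` with truth columns.
#' @export
generate_products <- function(scenario = default_study_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "fopnl_scenario"))
  set.seed(seed)
  sub <- scenario$subgroups
  cells <- scenario$cells[scenario$cells$n > 0, ]
  rows <- cells[rep(seq_len(nrow(cells)), cells$n), c("subgroup", "year")]
  n <- nrow(rows)
  si <- match(rows$subgroup, sub$subgroup)

  basis <- sub$basis[si]
  bev <- basis == "per100mL"
  milkish <- rows$subgroup %in% c("white_milk", "flavored_milk", "soy_milk",
                                  "nut_cereal_milk", "malt_chocolate_drink")

  energy <- rlnorm(n, ifelse(bev, log(150), log(1400)), 0.35)
  fat <- rlnorm(n, ifelse(bev, log(0.6), log(5)), 0.4)
  satfat <- fat * runif(n, 0.2, 0.6)
  protein <- rlnorm(n, ifelse(milkish, log(3), ifelse(bev, log(1.2), log(7))),
                    ifelse(milkish, 0.3, 0.45))
  sugar <- rlnorm(n, ifelse(bev, log(4), log(7)), 0.6)
  sodium <- rlnorm(n, ifelse(bev, log(30), log(150)), 0.45)
  fiber <- rlnorm(n, ifelse(bev, log(0.3), log(1.5)), 0.6)

  # overwrite the binding nutrient with its calibrated distribution
  binding_draw <- rlnorm(n, sub$binding_meanlog[si], sub$binding_sdlog[si])
  bn <- sub$nutrient[si]
  sugar[bn == "sugar_g"] <- binding_draw[bn == "sugar_g"]
  sodium[bn == "sodium_mg"] <- binding_draw[bn == "sodium_mg"]
  carb <- sugar + ifelse(bev, 1, 25)

  fiber_missing <- !bev & runif(n) < scenario$fiber_missing_p
  fiber[bev] <- 0

  # ground-truth eligibility: naive per-condition loop, independent of the
  # vectorized rules engine
  panel_lookup <- list(energy_kj = energy, total_fat_g = fat, sat_fat_g = satfat,
                       protein_g = protein, carb_g = carb, sugar_g = sugar,
                       fiber_g = fiber, sodium_mg = sodium)
  serving <- sub$serving_size[si]
  true_eligible <- rep(TRUE, n)
  conds <- scenario$criteria$conditions
  for (j in seq_len(nrow(conds))) {
    in_sg <- rows$subgroup == conds$subgroup[j]
    if (!any(in_sg)) next
    v <- panel_lookup[[conds$nutrient[j]]][in_sg]
    if (conds$basis[j] == "per_serving") v <- v * serving[in_sg] / 100
    ok <- if (conds$cmp[j] == "le") v <= conds$threshold[j] else v >= conds$threshold[j]
    true_eligible[in_sg] <- true_eligible[in_sg] & ok
  }

  grp <- scenario$groups
  gi <- match(sub$reporting_group[si], grp$reporting_group)
  x <- rows$year - min(scenario$years) + 1
  p_disp <- pmin(1, pmax(0, grp$u[gi] + grp$slope[gi] * (x - grp$x_mean[gi])))
  displayed <- ifelse(true_eligible, runif(n) < p_disp,
                      runif(n) < scenario$anomaly_rate)

  firm_w <- 1 / seq_len(scenario$n_firms)^scenario$zipf_s
  firm <- sample.int(scenario$n_firms, n, replace = TRUE, prob = firm_w)

  minors_by_sub <- split(names(scenario$map$minor_to_subgroup),
                         unname(scenario$map$minor_to_subgroup))
  minor <- vapply(rows$subgroup, function(sg) minors_by_sub[[sg]][1], character(1))
  major <- unname(scenario$map$minor_to_major[minor])

  batch <- record_batch(tibble::tibble(
    barcode = sprintf("885%09d", seq_len(n)),
    package_descriptor = "standard pack",
    release_year = rows$year,
    product_name = paste0(gsub("_", " ", rows$subgroup), " #", seq_len(n)),
    manufacturer = sprintf("firm_%04d", firm),
    gnpd_major = major,
    gnpd_minor = minor,
    ingredients = unname(.ingredient_templates[rows$subgroup]),
    thcl_displayed = displayed,
    basis = basis,
    serving_size = serving,
    energy_kj = energy, total_fat_g = fat, sat_fat_g = satfat,
    protein_g = protein, carb_g = carb, sugar_g = sugar,
    fiber_g = ifelse(fiber_missing, NA_real_, fiber),
    sodium_mg = sodium,
    true_eligible = true_eligible,
    true_display_p = ifelse(true_eligible, p_disp, scenario$anomaly_rate),
    true_fiber_g = fiber
  ), provenance = sprintf("synthetic scenario (seed %d)", seed))
  batch
}

#' Run the full annotation pipeline on a batch
#'
#' Categorize, impute fiber and FVNL, score with the HSR engine and
#' classify eligibility, in order. This is the per-batch analysis surface
#' used by the reports and by the acceptance script.
#'
#' @param batch A [record_batch()].
#' @param map,criteria,tables,lexicon Configuration objects; shipped assets
#'   by default.
#' @return The batch with all annotation columns.
#' @export
annotate_batch <- function(batch, map = read_category_map(),
                           criteria = read_criteria(),
                           tables = read_hsr_tables(),
                           lexicon = read_lexicon()) {
  batch |>
    assign_category(map) |>
    impute_fiber(lexicon = lexicon) |>
    impute_fvnl(lexicon = lexicon) |>
    score_hsr(tables) |>
    check_eligibility_batch(criteria)
}
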