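# Table-driven Health-Star-Rating-style nutrient profiling engine.
#
# Four steps: (1) baseline points for energy, saturated fat, total sugars
# and sodium per 100 g/mL; (2) modifying points for FVNL%, protein and
# fiber (protein subject to the cap rule); (3) final score = baseline -
# modifying; (4) per-category score -> half-star matrix, 0.5 to 5.0 stars,
# higher = healthier within category. Logic is table-driven so a table
# revision never touches code.

#' Load an HSR point-table asset
#'
#' @param path YAML tables file; defaults to the shipped version-stamped
#'   asset. See the asset header for the banding conventions.
#' @return A `fopnl_hsr_tables` list; band vectors are ascending lower
#'   edges (closed on the lower edge, open above, saturating at the top).
#' @export
read_hsr_tables <- function(path = fopnl_asset("hsr_tables_v7.yaml")) {
  tb <- yaml::read_yaml(path)
  tb$baseline$energy_kj <- lapply(tb$baseline$energy_kj, function(v) as.numeric(unlist(v)))
  for (nm in c("sat_fat_g", "sugar_g", "sodium_mg")) {
    tb$baseline[[nm]] <- as.numeric(unlist(tb$baseline[[nm]]))
  }
  for (nm in c("fvnl_pct", "protein_g", "fiber_g")) {
    tb$modifying[[nm]] <- as.numeric(unlist(tb$modifying[[nm]]))
  }
  tb$star_matrix <- lapply(tb$star_matrix, function(v) as.numeric(unlist(v)))
  tb$grade_map <- lapply(tb$grade_map, function(v) as.numeric(unlist(v)))
  for (v in c(tb$baseline$energy_kj, tb$baseline[-1], tb$modifying[1:3], tb$star_matrix)) {
    stopifnot(is.numeric(v), !anyNA(v), !is.unsorted(v, strictly = TRUE))
  }
  structure(tb, class = "fopnl_hsr_tables")
}

#' @export
print.fopnl_hsr_tables <- function(x, ...) {
  cat(sprintf("<fopnl_hsr_tables %s> categories: %s\n", x$version,
              paste(names(x$star_matrix), collapse = ", ")))
  invisible(x)
}

# closed-lower band lookup: points = number of band lower-edges <= x
.band_points <- function(x, bounds) {
  pts <- findInterval(x, bounds)
  pts[is.na(x)] <- 0L
  as.integer(pts)
}

#' Assign the HSR category of a product
#'
#' Beverages route to Category 1 (non-dairy) or 1D (dairy); foods to 2 or
#' 2D. The subgroup hint from the category map decides first; records
#' without a hint fall back to basis (beverage vs food) plus a dairy
#' ingredient scan. Oils/spreads and cheese style subgroups carry an
#' `unscored` hint and are never scored.
#'
#' @param hsr_hint Character vector of subgroup hints
#'   (`"1"`, `"1D"`, `"2"`, `"2D"`, `"unscored"`, or NA).
#' @param basis `"per100g"`/`"per100mL"` vector used for the fallback.
#' @param dairy Logical vector (dairy-based product) for the fallback.
#' @return Character vector of HSR categories.
#' @export
assign_hsr_category <- function(hsr_hint, basis, dairy = FALSE) {
  n <- max(length(hsr_hint), length(basis))
  hsr_hint <- rep_len(hsr_hint, n); basis <- rep_len(basis, n)
  dairy <- rep_len(dairy, n)
  fallback <- ifelse(basis == "per100mL",
                     ifelse(dairy, "1D", "1"),
                     ifelse(dairy, "2D", "2"))
  out <- ifelse(is.na(hsr_hint), fallback, hsr_hint)
  bad <- !out %in% c("1", "1D", "2", "2D", "unscored")
  if (any(bad)) stop("unknown HSR category hint: ", paste(unique(out[bad]), collapse = ", "))
  out
}

#' Baseline points
#'
#' Sum of the energy, saturated fat, total sugars and sodium band lookups.
#' Beverage categories (1, 1D) use the finer beverage energy bands. Values
#' above the top band saturate at the top band's points; missing values
#' contribute 0.
#'
#' @param panel Data frame with `energy_kj`, `sat_fat_g`, `sugar_g`,
#'   `sodium_mg` per 100 basis-units.
#' @param tables A [read_hsr_tables()] object.
#' @param category HSR category vector (`"1"`, `"1D"`, `"2"`, `"2D"`).
#' @return Integer vector of baseline points.
#' @export
baseline_points <- function(panel, tables = read_hsr_tables(), category = "2") {
  category <- rep_len(category, nrow(panel))
  bev <- category %in% c("1", "1D")
  e <- integer(nrow(panel))
  e[bev]  <- .band_points(panel$energy_kj[bev],  tables$baseline$energy_kj$beverage)
  e[!bev] <- .band_points(panel$energy_kj[!bev], tables$baseline$energy_kj$food)
  e +
    .band_points(panel$sat_fat_g, tables$baseline$sat_fat_g) +
    .band_points(panel$sugar_g,   tables$baseline$sugar_g) +
    .band_points(panel$sodium_mg, tables$baseline$sodium_mg)
}

#' Combined FVNL percentage
#'
#' Concentrated FVNL counts double through the configured combination
#' weighting: `100 * (nonconc + w * conc) / (100 + (w - 1) * conc)`, so a
#' sole-ingredient concentrate still reaches 100%.
#'
#' @param nonconc_pct,conc_pct Percent 0-100 (NA treated as 0).
#' @param tables A [read_hsr_tables()] object (supplies the weight `w`).
#' @return Numeric percent in \[0, 100\].
#' @export
combined_fvnl_pct <- function(nonconc_pct, conc_pct, tables = read_hsr_tables()) {
  n <- ifelse(is.na(nonconc_pct), 0, nonconc_pct)
  c_ <- ifelse(is.na(conc_pct), 0, conc_pct)
  w <- tables$modifying$conc_weight
  pmin(100, 100 * (n + w * c_) / (100 + (w - 1) * c_))
}

#' Modifying points
#'
#' V points from combined FVNL%, P points from protein, F points from
#' fiber. Protein points count only while the cap rule allows: baseline
#' below the cap threshold, or V points at or above the required level.
#'
#' @inheritParams baseline_points
#' @param baseline Integer vector from [baseline_points()].
#' @return Tibble with integer columns `v`, `p`, `f`.
#' @export
modifying_points <- function(panel, tables = read_hsr_tables(),
                             baseline = baseline_points(panel, tables),
                             category = "2") {
  v <- .band_points(combined_fvnl_pct(panel$fvnl_nonconc_pct,
                                      panel$fvnl_conc_pct, tables),
                    tables$modifying$fvnl_pct)
  p <- .band_points(panel$protein_g, tables$modifying$protein_g)
  f <- .band_points(panel$fiber_g, tables$modifying$fiber_g)
  capped <- baseline >= tables$protein_cap$baseline_threshold &
    v < tables$protein_cap$v_required
  p[capped] <- 0L
  tibble::tibble(v = v, p = p, f = f)
}

#' Map final scores to half-star ratings
#'
#' Per-category monotone matrix: stars = 5.0 minus half a star per matrix
#' cutoff at or below the score. Scores below the lowest cutoff give 5.0;
#' above the highest give 0.5.
#'
#' @param final_score Integer vector (baseline minus modifying points).
#' @param category HSR category vector; `"unscored"` yields NA.
#' @param tables A [read_hsr_tables()] object.
#' @return Numeric vector in `{0.5, 1.0, ..., 5.0}` (NA when unscored).
#' @export
score_to_stars <- function(final_score, category, tables = read_hsr_tables()) {
  category <- rep_len(category, length(final_score))
  out <- rep(NA_real_, length(final_score))
  for (cat_ in intersect(unique(category), names(tables$star_matrix))) {
    i <- which(category == cat_)
    out[i] <- 5.0 - 0.5 * findInterval(final_score[i], tables$star_matrix[[cat_]])
  }
  out
}

#' Map half-star ratings to a 5-grade letter
#'
#' A: 4.5-5.0 stars; B: 3.0-4.0; C: 2.0-2.5; D: 1.0-1.5; E: 0.5 (shipped
#' grade map, configurable through the tables asset).
#'
#' @param stars Numeric vector of half-star ratings.
#' @param tables A [read_hsr_tables()] object.
#' @return Character vector of grades.
#' @export
hsr_to_grade <- function(stars, tables = read_hsr_tables()) {
  lut <- unlist(lapply(names(tables$grade_map), function(g) {
    setNames(rep(g, length(tables$grade_map[[g]])),
             format(tables$grade_map[[g]], nsmall = 1))
  }))
  unname(lut[format(stars, nsmall = 1)])
}

#' Score a batch with the HSR engine
#'
#' Runs the four scoring steps over every in-scope record: category
#' assignment (subgroup hint first), baseline points, modifying points with
#' the protein cap, final score and star rating. Records with an
#' `unscored` category get NA stars and an explicit `hsr_scored = FALSE`.
#'
#' @param batch A categorized, imputed [record_batch()].
#' @param tables A [read_hsr_tables()] object.
#' @return The batch with columns `hsr_category`, `hsr_baseline`, `hsr_v`,
#'   `hsr_p`, `hsr_f`, `hsr_score`, `hsr_stars`, `hsr_grade`,
#'   `hsr_scored`, `hsr_table_version`.
#' @export
score_hsr <- function(batch, tables = read_hsr_tables()) {
  stopifnot(inherits(batch, "fopnl_batch"))
  category <- assign_hsr_category(batch$hsr_category, batch$basis)
  scored <- category != "unscored" & !is.na(category)
  base <- baseline_points(batch, tables, category)
  mods <- modifying_points(batch, tables, base, category)
  batch$hsr_category <- category
  batch$hsr_baseline <- ifelse(scored, base, NA_integer_)
  batch$hsr_v <- ifelse(scored, mods$v, NA_integer_)
  batch$hsr_p <- ifelse(scored, mods$p, NA_integer_)
  batch$hsr_f <- ifelse(scored, mods$f, NA_integer_)
  batch$hsr_score <- ifelse(scored, base - (mods$v + mods$p + mods$f), NA_integer_)
  batch$hsr_stars <- ifelse(scored,
                            score_to_stars(batch$hsr_score, category, tables),
                            NA_real_)
  batch$hsr_grade <- ifelse(scored, hsr_to_grade(batch$hsr_stars, tables), NA_character_)
  batch$hsr_scored <- scored
  batch$hsr_table_version <- tables$version
  batch
}
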