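# Config-driven logo eligibility: per-subgroup conjunctive nutrient
# conditions evaluated on the standardized panel (or rescaled to the
# declared serving for per-serving thresholds).

#' Load a criteria registry
#'
#' @param path YAML registry; defaults to the shipped versioned asset
#'   seeded with the published thresholds (sugar-sweetened beverage sugar
#'   6.0 g/100 mL, water-based sauce sodium 5000-6000 mg/100 mL, instant
#'   noodle/porridge sodium 1000 mg/50 g serving) plus placeholder entries
#'   for the remaining subgroups.
#' @return A `fopnl_criteria` object with a tidy `$conditions` tibble
#'   (`subgroup`, `nutrient`, `cmp`, `threshold`, `basis`).
#' @export
read_criteria <- function(path = fopnl_asset("thcl_criteria.yaml")) {
  raw <- yaml::read_yaml(path)
  cond <- purrr::imap_dfr(raw$subgroups, function(x, nm) {
    purrr::map_dfr(x$conditions, function(cn) {
      tibble::tibble(subgroup = nm, nutrient = cn$nutrient, cmp = cn$cmp,
                     threshold = as.numeric(cn$threshold), basis = cn$basis,
                     anchored = isTRUE(cn$anchored))
    })
  })
  stopifnot(all(cond$cmp %in% c("le", "ge")),
            all(cond$basis %in% c("per100", "per_serving")),
            all(cond$nutrient %in% panel_nutrients()))
  structure(list(version = raw$version, conditions = cond), class = "fopnl_criteria")
}

#' @export
print.fopnl_criteria <- function(x, ...) {
  cat(sprintf("<fopnl_criteria %s> %d conditions over %d subgroups\n",
              x$version, nrow(x$conditions), length(unique(x$conditions$subgroup))))
  invisible(x)
}

.eval_conditions <- function(panel_row, conds) {
  val <- vapply(seq_len(nrow(conds)), function(j) {
    v <- panel_row[[conds$nutrient[j]]]
    if (conds$basis[j] == "per_serving") {
      ss <- panel_row[["serving_size"]]
      if (is.na(ss)) return(NA_real_)
      v <- v * ss / 100
    }
    as.numeric(v)
  }, numeric(1))
  ifelse(conds$cmp == "le", val <= conds$threshold, val >= conds$threshold)
}

#' Check logo eligibility of a single product
#'
#' Evaluates every condition of the product's subgroup on the standardized
#' panel; all conditions are conjunctive. Missing criteria for the subgroup
#' give a flagged not-eligible result; a missing nutrient or serving size
#' fails the affected condition.
#'
#' @param panel_row One-row data frame (or list) carrying the standardized
#'   panel columns and `serving_size`.
#' @param subgroup Scheme subgroup id.
#' @param criteria A [read_criteria()] registry.
#' @return A list: `eligible` (logical), `failed_conditions` (tibble of
#'   failing rows), `no_criteria` (logical), `criteria_version`.
#' @examples
#' crit <- read_criteria()
#' check_eligibility(list(sugar_g = 5, sodium_mg = 40, serving_size = NA_real_),
#'                   "carbonated_soft_drink", crit)$eligible
#' @export
check_eligibility <- function(panel_row, subgroup, criteria = read_criteria()) {
  conds <- criteria$conditions[criteria$conditions$subgroup == subgroup, ]
  if (!nrow(conds)) {
    return(list(eligible = FALSE, failed_conditions = conds,
                no_criteria = TRUE, criteria_version = criteria$version))
  }
  if (is.list(panel_row) && !is.data.frame(panel_row)) {
    missing <- setdiff(c(unique(conds$nutrient), "serving_size"), names(panel_row))
    panel_row[missing] <- NA_real_
  }
  ok <- .eval_conditions(panel_row, conds)
  ok[is.na(ok)] <- FALSE
  list(eligible = all(ok), failed_conditions = conds[!ok, ],
       no_criteria = FALSE, criteria_version = criteria$version)
}

#' Check logo eligibility across a batch
#'
#' Vectorized conjunction of the registry conditions per subgroup.
#' Products out of scheme scope, outside their criteria window, or in a
#' subgroup without criteria are not eligible and flagged accordingly.
#'
#' @param batch A categorized, standardized [record_batch()].
#' @param criteria A [read_criteria()] registry.
#' @return The batch with `eligible` (logical), `no_criteria`,
#'   `criteria_version`, and the display-consistency tag from
#'   [uptake_flag()].
#' @export
check_eligibility_batch <- function(batch, criteria = read_criteria()) {
  stopifnot(inherits(batch, "fopnl_batch"), "subgroup" %in% names(batch))
  n <- nrow(batch)
  pass <- rep(TRUE, n)
  has_crit <- batch$subgroup %in% unique(criteria$conditions$subgroup)
  for (sg in unique(batch$subgroup[has_crit])) {
    rows <- which(batch$subgroup == sg & !is.na(batch$subgroup))
    conds <- criteria$conditions[criteria$conditions$subgroup == sg, ]
    for (j in seq_len(nrow(conds))) {
      v <- batch[[conds$nutrient[j]]][rows]
      if (conds$basis[j] == "per_serving") v <- v * batch$serving_size[rows] / 100
      ok <- if (conds$cmp[j] == "le") v <= conds$threshold[j] else v >= conds$threshold[j]
      ok[is.na(ok)] <- FALSE
      pass[rows] <- pass[rows] & ok
    }
  }
  batch$no_criteria <- !has_crit
  batch$eligible <- pass & has_crit & batch$in_scheme_scope & batch$in_window
  batch$criteria_version <- criteria$version
  batch$display_tag <- uptake_flag(batch$thcl_displayed, batch$eligible)
  batch
}

#' Display-consistency cross-tab tag
#'
#' @param displayed Logical: product shows the logo on pack.
#' @param eligible Logical: product meets its subgroup criteria.
#' @return Character tag: `displayed-eligible`, `displayed-ineligible`
#'   (anomaly), `eligible-non-adopter`, or `ineligible-non-adopter`.
#' @export
uptake_flag <- function(displayed, eligible) {
  dplyr::case_when(
    displayed & eligible ~ "displayed-eligible",
    displayed & !eligible ~ "displayed-ineligible",
    !displayed & eligible ~ "eligible-non-adopter",
    .default = "ineligible-non-adopter"
  )
}
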