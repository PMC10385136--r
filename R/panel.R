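# Nutrition information panel (NIP) standardization.
#
# Label data arrive per serving and/or per 100 g/mL, energy in kcal or kJ,
# calcium/iron as %RDA. Everything downstream (HSR scoring, eligibility)
# assumes one canonical basis: per 100 g (foods) or per 100 mL (beverages),
# energy in kJ, minerals in mg.

#' Canonical nutrient column names of a standardized panel
#'
#' @return Character vector of panel column names as used throughout the
#'   package: energy in kJ, macronutrients in g, sodium/calcium/iron in mg,
#'   FVNL shares in percent, all per 100 basis-units.
#' @export
panel_nutrients <- function() {
  c("energy_kj", "total_fat_g", "sat_fat_g", "protein_g", "carb_g",
    "sugar_g", "fiber_g", "sodium_mg", "calcium_mg", "iron_mg")
}

#' Package configuration defaults
#'
#' Central place for the constants the standardization step needs but the
#' scheme documents leave to the implementer: the rounding rule for
#' "less than" declarations and the RDA reference values used to convert
#' calcium/iron %RDA declarations to mg (Thai RDI-style references).
#'
#' @param less_than_rule How a declared "<x" is resolved to a number:
#'   `"nearest"` (round x to the nearest whole number, half up) or
#'   `"ceiling"`.
#' @param rda_mg Named numeric vector of RDA reference values in mg used for
#'   %RDA to mg conversion.
#' @param kcal_to_kj Energy conversion factor (SI).
#' @return A named list of settings.
#' @export
fopnl_config <- function(less_than_rule = c("nearest", "ceiling"),
                         rda_mg = c(calcium = 800, iron = 15),
                         kcal_to_kj = 4.184) {
  less_than_rule <- match.arg(less_than_rule)
  stopifnot(is.numeric(rda_mg), all(rda_mg > 0), kcal_to_kj > 0)
  list(less_than_rule = less_than_rule, rda_mg = rda_mg, kcal_to_kj = kcal_to_kj)
}

#' Resolve "less than" nutrient declarations
#'
#' NIP values declared as "less than" (e.g. `"<1.0 g"`) are adjusted to the
#' whole number closest to the stated bound before analysis; plain numeric
#' declarations pass through unchanged. The canonical example is fiber
#' declared `<1.0` g/100 g becoming `1.0` g/100 g.
#'
#' @param declared Character or numeric vector; character entries may be
#'   plain numbers or `"<x"` tokens (whitespace and a trailing unit are
#'   tolerated).
#' @param rule `"nearest"` rounds the bound half-up to the nearest whole
#'   number (`"<0.4"` becomes 0); `"ceiling"` always rounds up.
#' @return A tibble with columns `value` (numeric) and `adjusted` (logical,
#'   `TRUE` where a "<" token was resolved).
#' @examples
#' apply_less_than_rule(c("<1.0", "2.5", "<0.4"))
#' @export
apply_less_than_rule <- function(declared, rule = c("nearest", "ceiling")) {
  rule <- match.arg(rule)
  if (is.numeric(declared)) {
    return(tibble::tibble(value = as.numeric(declared),
                          adjusted = rep(FALSE, length(declared))))
  }
  txt <- trimws(as.character(declared))
  is_lt <- startsWith(txt, "<")
  num_part <- sub("^<\\s*", "", txt)
  num_part <- sub("\\s*[a-zA-Z%/]+.*$", "", num_part)
  val <- suppressWarnings(as.numeric(num_part))
  if (anyNA(val[!is.na(declared)])) {
    bad <- txt[is.na(val) & !is.na(declared)]
    stop("unparseable nutrient declaration(s): ", paste(bad, collapse = ", "))
  }
  out <- val
  # round-half-up at integer resolution; ceiling variant available by config
  out[is_lt] <- if (rule == "nearest") floor(val[is_lt] + 0.5) else ceiling(val[is_lt])
  tibble::tibble(value = out, adjusted = is_lt & !is.na(val))
}

# Raw-declaration keys accepted by standardize_panel and their canonical
# panel columns. Calcium/iron may arrive as %RDA or as mg.
.raw_keys <- c(
  energy = "energy_kj", total_fat = "total_fat_g", saturated_fat = "sat_fat_g",
  protein = "protein_g", total_carbohydrate = "carb_g", total_sugar = "sugar_g",
  fiber = "fiber_g", sodium = "sodium_mg",
  calcium_mg = "calcium_mg", iron_mg = "iron_mg",
  calcium_pct_rda = "calcium_mg", iron_pct_rda = "iron_mg",
  fvnl_nonconc_pct = "fvnl_nonconc_pct", fvnl_conc_pct = "fvnl_conc_pct"
)

#' Standardize a raw nutrient declaration to per-100 basis-units
#'
#' Rescales a declared NIP to per 100 g or per 100 mL, converts energy to kJ
#' (factor 4.184 kJ/kcal), resolves "less than" tokens, and converts
#' calcium/iron declared as %RDA to mg using the configured RDA references.
#' FVNL percentages are compositional shares and are never rescaled.
#'
#' @param raw Named list or vector of declared values. Recognized names:
#'   `energy`, `total_fat`, `saturated_fat`, `protein`, `total_carbohydrate`,
#'   `total_sugar`, `fiber`, `sodium`, `calcium_mg`/`calcium_pct_rda`,
#'   `iron_mg`/`iron_pct_rda`, `fvnl_nonconc_pct`, `fvnl_conc_pct`. Values
#'   may be numeric or "<x" strings.
#' @param declared_basis `"per100"` if the declaration is already per
#'   100 g/mL, `"per_serving"` if per declared serving.
#' @param serving_size Serving size in g or mL; required when
#'   `declared_basis = "per_serving"`, and carried through either way so
#'   per-serving eligibility criteria can be evaluated later.
#' @param energy_unit Unit of the declared energy value.
#' @param basis Physical form of the product: `"per100g"` (foods) or
#'   `"per100mL"` (beverages).
#' @param config See [fopnl_config()].
#' @return A one-row tibble with the [panel_nutrients()] columns plus
#'   `basis`, `serving_size`, `lt_adjusted` (any "<" resolved),
#'   `panel_quality` (empty string, or a ";"-separated list of soft
#'   validation flags such as `sat_fat>total_fat`).
#' @examples
#' standardize_panel(
#'   list(energy = 120, total_sugar = "4.5", sodium = 500),
#'   declared_basis = "per_serving", serving_size = 50,
#'   energy_unit = "kcal", basis = "per100g"
#' )
#' @export
standardize_panel <- function(raw,
                              declared_basis = c("per100", "per_serving"),
                              serving_size = NULL,
                              energy_unit = c("kJ", "kcal"),
                              basis = c("per100g", "per100mL"),
                              config = fopnl_config()) {
  declared_basis <- match.arg(declared_basis)
  energy_unit <- match.arg(energy_unit)
  basis <- match.arg(basis)
  raw <- as.list(raw)
  unknown <- setdiff(names(raw), names(.raw_keys))
  if (length(unknown)) {
    stop("unknown nutrient key(s): ", paste(unknown, collapse = ", "))
  }
  if (declared_basis == "per_serving" &&
      (is.null(serving_size) || !is.finite(serving_size) || serving_size <= 0)) {
    stop("no usable NIP: per-serving declaration without a positive serving size")
  }

  cols <- c(panel_nutrients(), "fvnl_nonconc_pct", "fvnl_conc_pct")
  out <- setNames(as.list(rep(NA_real_, length(cols))), cols)
  lt_any <- FALSE
  for (key in names(raw)) {
    if (is.null(raw[[key]]) || (length(raw[[key]]) == 1 && is.na(raw[[key]]))) next
    res <- apply_less_than_rule(raw[[key]], rule = config$less_than_rule)
    val <- res$value
    lt_any <- lt_any || any(res$adjusted)
    if (val < 0) stop("negative nutrient value for ", key)
    col <- .raw_keys[[key]]
    if (key %in% c("fvnl_nonconc_pct", "fvnl_conc_pct")) {
      if (val > 100) stop(key, " must lie in [0, 100]")
      out[[col]] <- val
      next
    }
    if (key == "calcium_pct_rda") val <- val / 100 * config$rda_mg[["calcium"]]
    if (key == "iron_pct_rda")    val <- val / 100 * config$rda_mg[["iron"]]
    if (key == "energy" && energy_unit == "kcal") val <- val * config$kcal_to_kj
    if (declared_basis == "per_serving") val <- val * 100 / serving_size
    out[[col]] <- val
  }

  flags <- character(0)
  if (!is.na(out$sat_fat_g) && !is.na(out$total_fat_g) &&
      out$sat_fat_g > out$total_fat_g + 1e-9) {
    flags <- c(flags, "sat_fat>total_fat")
  }
  if (!is.na(out$sugar_g) && !is.na(out$carb_g) &&
      out$sugar_g > out$carb_g + 1e-9) {
    flags <- c(flags, "sugar>carb")
  }

  tibble::tibble(
    basis = basis,
    serving_size = if (is.null(serving_size)) NA_real_ else as.numeric(serving_size),
    !!!out,
    lt_adjusted = lt_any,
    fiber_imputed = FALSE,
    fvnl_imputed = FALSE,
    panel_quality = paste(flags, collapse = ";")
  )
}
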