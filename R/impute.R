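# Fiber and FVNL estimation from ordered ingredient lists.
#
# Thai labels need not declare fiber or fruit/vegetable/nut/legume (FVNL)
# content, so both are estimated: fiber from same-subgroup donors, FVNL by a
# four-band decision tree over the position of FVNL ingredients in the
# (predominance-ordered) ingredient list.

#' Load the ingredient-scanning lexicon
#'
#' @param path YAML lexicon; defaults to the shipped asset. Contains
#'   fiber-source tokens, FVNL name fragments, concentrated-form markers and
#'   the minor-additive list used to operationalize "does not substantially
#'   contribute to the product's weight".
#' @return A named list of character vectors.
#' @export
read_lexicon <- function(path = fopnl_asset("fvnl_lexicon.yaml")) {
  lex <- yaml::read_yaml(path)
  lapply(lex[c("fiber_sources", "fvnl_tokens", "concentrated_markers",
               "minor_additives")], tolower)
}

.match_any <- function(x, tokens) {
  if (!length(x)) return(logical(0))
  hit <- rep(FALSE, length(x))
  for (tok in tokens) hit <- hit | grepl(tok, x, fixed = TRUE)
  hit
}

#' Flag fiber and FVNL source ingredients
#'
#' Case-insensitive token scan over an ordered ingredient list, flagging
#' fiber-containing ingredients (inulin, psyllium, pectin,
#' fructooligosaccharides, brans, ...), FVNL ingredients, their concentrated
#' forms, and minor additives.
#'
#' @param ingredients Character vector, predominance order (rank 1 first).
#' @param lexicon See [read_lexicon()].
#' @return A tibble with one row per ingredient: `ingredient`, `position`,
#'   `fiber_source`, `fvnl_source`, `fvnl_concentrated`, `minor_additive`.
#'   An empty list returns zero rows with a warning.
#' @examples
#' detect_fvnl_ingredients(c("water", "inulin", "sugar"))
#' @export
detect_fvnl_ingredients <- function(ingredients, lexicon = read_lexicon()) {
  if (is.null(ingredients) || !length(ingredients)) {
    warning("empty ingredient list; no source flags")
    ingredients <- character(0)
  }
  low <- tolower(trimws(ingredients))
  fvnl <- .match_any(low, lexicon$fvnl_tokens)
  tibble::tibble(
    ingredient = as.character(ingredients),
    position = seq_along(low),
    fiber_source = .match_any(low, lexicon$fiber_sources),
    fvnl_source = fvnl,
    fvnl_concentrated = fvnl & .match_any(low, lexicon$concentrated_markers),
    minor_additive = .match_any(low, lexicon$minor_additives)
  )
}

#' Allocate FVNL percentage bands from an ingredient list
#'
#' Four-band decision tree, most to least specific; exactly one rule fires:
#'
#' 1. FVNL is the sole weight-contributing ingredient: concentrated and
#'    non-concentrated both 100%.
#' 2. FVNL is the first ingredient and all non-FVNL ingredients are minor
#'    additives: concentrated band >=67%, non-concentrated band >80%.
#' 3. FVNL is within the first three (concentrated) / first two
#'    (non-concentrated) ingredients: bands >=25% / >40%.
#' 4. Otherwise: bands <25% / <=40%.
#'
#' The assigned percentage is the band's lower bound by default
#' (conservative for downstream modifying points); midpoint by config.
#'
#' @param ingredients Character vector in predominance order, or a flags
#'   tibble from [detect_fvnl_ingredients()].
#' @param lexicon See [read_lexicon()].
#' @param band_value `"lower"` or `"midpoint"` band representative.
#' @return One-row tibble: `conc_band`, `nonconc_band`,
#'   `assigned_conc_pct`, `assigned_nonconc_pct`, `rule` (which rule fired).
#' @examples
#' allocate_fvnl(c("orange juice"))
#' allocate_fvnl(c("water", "sugar", "carrot juice"))
#' @export
allocate_fvnl <- function(ingredients, lexicon = read_lexicon(),
                          band_value = c("lower", "midpoint")) {
  band_value <- match.arg(band_value)
  flags <- if (is.data.frame(ingredients)) ingredients else
    suppressWarnings(detect_fvnl_ingredients(ingredients, lexicon))
  n <- nrow(flags)
  fvnl <- flags$fvnl_source
  minor <- flags$minor_additive
  first_fvnl <- if (any(fvnl)) min(flags$position[fvnl]) else Inf

  if (n > 0 && all(fvnl)) {
    rule <- "sole-ingredient"
    conc_band <- "eq100"; nonconc_band <- "eq100"
  } else if (is.finite(first_fvnl) && first_fvnl == 1 && all(fvnl | minor)) {
    rule <- "first-ingredient-minor-rest"
    conc_band <- "ge67"; nonconc_band <- "gt80"
  } else if (first_fvnl <= 3 || first_fvnl <= 2) {
    # concentrated: third ingredient or higher; non-concentrated: second
    rule <- "top-ranked"
    conc_band <- if (first_fvnl <= 3) "ge25" else "lt25"
    nonconc_band <- if (first_fvnl <= 2) "gt40" else "le40"
  } else {
    rule <- "default-low"
    conc_band <- "lt25"; nonconc_band <- "le40"
  }

  band_pct <- function(band) {
    lower <- c(eq100 = 100, ge67 = 67, gt80 = 80, ge25 = 25, gt40 = 40,
               lt25 = 0, le40 = 0)[[band]]
    if (band_value == "lower") return(lower)
    upper <- c(eq100 = 100, ge67 = 100, gt80 = 100, ge25 = 67, gt40 = 80,
               lt25 = 25, le40 = 40)[[band]]
    (lower + upper) / 2
  }
  tibble::tibble(conc_band = conc_band, nonconc_band = nonconc_band,
                 assigned_conc_pct = band_pct(conc_band),
                 assigned_nonconc_pct = band_pct(nonconc_band),
                 rule = rule)
}

#' Impute missing fiber values from subgroup donors
#'
#' Products with a missing fiber declaration but a fiber-source ingredient
#' receive an estimate from products of the same subgroup that declare
#' fiber: for homogeneous subgroups the mean of declared non-zero fiber;
#' for heterogeneous subgroups the declared fiber of the most similar donor
#' (nearest energy per 100 basis-units, ties broken by lower barcode).
#' Declared values pass through untouched; products with neither a
#' declaration nor a fiber-source ingredient get fiber 0.
#'
#' @param batch A categorized [record_batch()] (needs `subgroup`).
#' @param homogeneous_subgroups Character vector of subgroups treated as
#'   homogeneous (category-mean strategy); others use donor matching.
#' @param lexicon See [read_lexicon()].
#' @return The batch with `fiber_g` filled, `fiber_imputed` flags, and a
#'   `fiber_strategy` column (`declared`, `category_mean`,
#'   `matched_product`, `zero`).
#' @export
impute_fiber <- function(batch,
                         homogeneous_subgroups = c("potato_chips", "dressing",
                                                   "wet_soup", "instant_soup"),
                         lexicon = read_lexicon()) {
  stopifnot(inherits(batch, "fopnl_batch"), "subgroup" %in% names(batch))
  has_fiber_src <- vapply(batch$ingredients, function(ing) {
    if (is.null(ing) || !length(ing)) return(FALSE)
    any(.match_any(tolower(ing), lexicon$fiber_sources))
  }, logical(1))

  declared <- !is.na(batch$fiber_g)
  batch$fiber_strategy <- ifelse(declared, "declared", NA_character_)
  batch$fiber_imputed <- !declared

  need <- which(!declared)
  for (i in need) {
    if (!has_fiber_src[i]) {
      batch$fiber_g[i] <- 0
      batch$fiber_strategy[i] <- "zero"
      next
    }
    sg <- batch$subgroup[i]
    donors <- which(declared & batch$subgroup == sg & !is.na(batch$subgroup))
    nz <- donors[batch$fiber_g[donors] > 0]
    if (!length(nz)) {
      warning("no fiber donors in subgroup ", sg, "; imputing 0")
      batch$fiber_g[i] <- 0
      batch$fiber_strategy[i] <- "zero"
    } else if (!is.na(sg) && sg %in% homogeneous_subgroups) {
      batch$fiber_g[i] <- mean(batch$fiber_g[nz])
      batch$fiber_strategy[i] <- "category_mean"
    } else {
      gap <- abs(batch$energy_kj[nz] - batch$energy_kj[i])
      gap[is.na(gap)] <- Inf
      best <- nz[order(gap, batch$barcode[nz])][1]
      batch$fiber_g[i] <- batch$fiber_g[best]
      batch$fiber_strategy[i] <- "matched_product"
    }
  }
  batch
}

#' Fill FVNL percentages across a batch
#'
#' Applies [allocate_fvnl()] to every record whose panel lacks declared
#' FVNL percentages; declared values pass through with
#' `fvnl_imputed = FALSE`.
#'
#' @inheritParams impute_fiber
#' @param band_value Passed to [allocate_fvnl()].
#' @return The batch with `fvnl_conc_pct`, `fvnl_nonconc_pct`,
#'   `fvnl_imputed`, and `fvnl_rule` filled.
#' @export
impute_fvnl <- function(batch, lexicon = read_lexicon(),
                        band_value = "lower") {
  stopifnot(inherits(batch, "fopnl_batch"))
  missing_fvnl <- is.na(batch$fvnl_nonconc_pct) & is.na(batch$fvnl_conc_pct)
  batch$fvnl_imputed <- missing_fvnl
  batch$fvnl_rule <- NA_character_
  # identical ingredient lists allocate identically; memoize by list key
  cache <- new.env(parent = emptyenv())
  for (i in which(missing_fvnl)) {
    ing <- batch$ingredients[[i]]
    key <- if (is.null(ing) || !length(ing)) "" else paste(ing, collapse = "")
    alloc <- cache[[key]]
    if (is.null(alloc)) {
      alloc <- if (key == "<none>") {
        tibble::tibble(assigned_conc_pct = 0, assigned_nonconc_pct = 0,
                       rule = "no-ingredients")
      } else {
        allocate_fvnl(ing, lexicon, band_value)
      }
      cache[[key]] <- alloc
    }
    batch$fvnl_conc_pct[i] <- alloc$assigned_conc_pct
    batch$fvnl_nonconc_pct[i] <- alloc$assigned_nonconc_pct
    batch$fvnl_rule[i] <- alloc$rule
  }
  batch$fvnl_conc_pct[is.na(batch$fvnl_conc_pct)] <- 0
  batch$fvnl_nonconc_pct[is.na(batch$fvnl_nonconc_pct)] <- 0
  batch
}
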