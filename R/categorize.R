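# Category crosswalk: launch-database minor categories -> scheme subgroups
# -> 18 reporting groups, plus the scheme-scope exclusion filter and the
# per-subgroup criteria start-year window.

#' Path to a shipped configuration asset
#' @param file Asset file name under `extdata/`.
#' @return Absolute path.
#' @export
fopnl_asset <- function(file) {
  path <- system.file("extdata", file, package = "fopnl")
  if (path == "") stop("asset not found: ", file)
  path
}

#' Load a category map
#'
#' Reads the YAML crosswalk shipped with the package (or a user-supplied
#' one): minor-category to subgroup edges, subgroup to reporting-group
#' edges, criteria start years, panel basis and HSR category hint per
#' subgroup, and the scheme-scope exclusion list.
#'
#' @param path YAML file; defaults to the shipped asset.
#' @return A `fopnl_category_map` list with a tidy `$subgroups` tibble,
#'   `$minor_to_subgroup` lookup, `$minor_to_major` lookup,
#'   `$excluded_minors` named vector and `$reporting_groups` character
#'   vector.
#' @export
read_category_map <- function(path = fopnl_asset("category_map.yaml")) {
  raw <- yaml::read_yaml(path)
  sub <- purrr::imap_dfr(raw$subgroups, function(x, nm) {
    tibble::tibble(subgroup = nm,
                   reporting_group = x$reporting_group,
                   start_year = as.integer(x$start_year),
                   hsr_category = as.character(x$hsr_category),
                   basis = x$basis,
                   anchored = isTRUE(x$anchored))
  })
  stopifnot(!anyDuplicated(sub$subgroup))
  if (!setequal(sub$reporting_group, raw$reporting_groups)) {
    stop("category map invalid: subgroup reporting groups do not match the declared roster")
  }
  structure(list(
    version = raw$version,
    reporting_groups = raw$reporting_groups,
    subgroups = sub,
    minor_to_subgroup = unlist(raw$minor_to_subgroup),
    minor_to_major = unlist(raw$minor_to_major),
    excluded_minors = unlist(raw$excluded_minors)
  ), class = "fopnl_category_map")
}

#' @export
print.fopnl_category_map <- function(x, ...) {
  cat(sprintf("<fopnl_category_map %s> %d minors -> %d subgroups -> %d reporting groups\n",
              x$version, length(x$minor_to_subgroup), nrow(x$subgroups),
              length(x$reporting_groups)))
  invisible(x)
}

#' Scheme-scope exclusion check
#'
#' Products outside the endorsement scheme's scope (drinking water, vinegar,
#' supplementary sports foods, infant foods and formulas, foods for special
#' medical purposes, vitamins and supplements) are excluded with a reason
#' tag; everything else returns `NA`.
#'
#' @param gnpd_minor Character vector of minor category codes.
#' @param map A [read_category_map()] object (the exclusion list is
#'   config-extensible through the YAML).
#' @return Character vector of exclusion reasons, `NA` where not excluded.
#' @export
apply_exclusions <- function(gnpd_minor, map = read_category_map()) {
  unname(map$excluded_minors[match(gnpd_minor, names(map$excluded_minors))])
}

#' Assign products to scheme subgroups and reporting groups
#'
#' Deterministic crosswalk on the minor category code. Minor categories on
#' the exclusion list are routed to exclusion; minors absent from the map
#' yield an `unmapped` status rather than a guess. Categorization depends
#' only on category codes and release year, never on nutrients.
#'
#' @param batch A [record_batch()].
#' @param map A [read_category_map()].
#' @return The batch with columns `subgroup`, `reporting_group`,
#'   `hsr_category`, `criteria_start_year`, `in_scheme_scope`,
#'   `in_window` (release year at or after the subgroup's criteria start
#'   year), `category_status` (one of `assigned-in-window`,
#'   `assigned-out-of-window`, `excluded`, `unmapped`) and `excluded`
#'   filled with reason tags.
#' @export
assign_category <- function(batch, map = read_category_map()) {
  stopifnot(inherits(batch, "fopnl_batch"))
  excl <- apply_exclusions(batch$gnpd_minor, map)
  sg <- unname(map$minor_to_subgroup[match(batch$gnpd_minor, names(map$minor_to_subgroup))])
  sg[!is.na(excl)] <- NA_character_
  idx <- match(sg, map$subgroups$subgroup)
  batch$subgroup <- sg
  batch$reporting_group <- map$subgroups$reporting_group[idx]
  batch$hsr_category <- map$subgroups$hsr_category[idx]
  batch$criteria_start_year <- map$subgroups$start_year[idx]
  map_basis <- map$subgroups$basis[idx]
  batch$basis <- ifelse(is.na(batch$basis), map_basis, batch$basis)
  batch$excluded <- ifelse(!is.na(excl), excl, batch$excluded)
  batch$in_scheme_scope <- is.na(excl) & !is.na(sg)
  batch$in_window <- eligibility_window(batch$release_year, batch$criteria_start_year)
  batch$category_status <- dplyr::case_when(
    !is.na(excl) ~ "excluded",
    is.na(sg) ~ "unmapped",
    batch$in_window ~ "assigned-in-window",
    .default = "assigned-out-of-window"
  )
  batch
}

#' Criteria eligibility window
#'
#' A product counts toward uptake denominators only once its subgroup has
#' published criteria: `release_year >= criteria_start_year`, inclusive at
#' the start year (the adoption year's launches are counted).
#'
#' @param release_year Integer vector.
#' @param start_year Integer vector (recycled), NA where no subgroup.
#' @return Logical vector; `FALSE` where either input is NA.
#' @export
eligibility_window <- function(release_year, start_year) {
  out <- release_year >= start_year
  out[is.na(out)] <- FALSE
  out
}

#' Mapping-gap report
#'
#' @param batch Output of [assign_category()].
#' @return Tibble of unmapped minor categories and their record counts.
#' @export
unmapped_report <- function(batch) {
  batch |>
    dplyr::filter(.data$category_status == "unmapped") |>
    dplyr::count(.data$gnpd_minor, name = "n_records") |>
    tibble::as_tibble()
}
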