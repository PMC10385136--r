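# Product record batches: a classed tibble, one row per barcode x package
# size, carrying identity, category codes, ingredient list, the standardized
# panel columns and the label-display flag.

.mandatory_cols <- c("barcode", "release_year", "gnpd_minor", "thcl_displayed")

.batch_col_order <- function() {
  c("barcode", "package_descriptor", "release_year", "product_name",
    "description", "manufacturer", "gnpd_major", "gnpd_minor", "ingredients",
    "thcl_displayed", "excluded", "basis", "serving_size", panel_nutrients(),
    "fvnl_nonconc_pct", "fvnl_conc_pct", "lt_adjusted", "fiber_imputed",
    "fvnl_imputed", "panel_quality")
}

#' Construct a product record batch
#'
#' A record batch is a tibble with one row per product (identity = barcode;
#' distinct package sizes of the same formulation carry distinct barcodes and
#' count as distinct products). Missing optional columns are added as NA;
#' extra columns are preserved as passthrough.
#'
#' @param records A data frame with at least `barcode`, `release_year`,
#'   `gnpd_minor`, `thcl_displayed`. `ingredients` may be a list-column of
#'   character vectors (ordered by predominance, rank 1 first) or a single
#'   `"; "`-delimited string column.
#' @param provenance Free-text source tag stored as an attribute.
#' @return A `fopnl_batch` tibble.
#' @export
record_batch <- function(records, provenance = "unspecified") {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(.mandatory_cols, names(records))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(records$barcode) | records$barcode == "")) {
    stop("schema error: empty barcode(s)")
  }
  records$barcode <- as.character(records$barcode)
  records$release_year <- as.integer(records$release_year)
  records$thcl_displayed <- as.logical(records$thcl_displayed)
  if (!"ingredients" %in% names(records)) {
    records$ingredients <- vector("list", nrow(records))
  }
  if (is.character(records$ingredients)) {
    records$ingredients <- strsplit(records$ingredients, ";\\s*")
  }
  for (col in setdiff(.batch_col_order(), names(records))) {
    records[[col]] <- switch(col,
      excluded = , basis = , panel_quality = , package_descriptor = ,
      product_name = , description = , manufacturer = ,
      gnpd_major = NA_character_,
      lt_adjusted = , fiber_imputed = , fvnl_imputed = NA,
      NA_real_)
  }
  extras <- setdiff(names(records), .batch_col_order())
  records <- records[, c(.batch_col_order(), extras)]
  yrs <- records$release_year
  structure(records,
            class = c("fopnl_batch", class(tibble::tibble()))) |>
    `attr<-`("provenance", provenance) |>
    `attr<-`("year_range", if (nrow(records)) range(yrs) else c(NA_integer_, NA_integer_))
}

#' @export
print.fopnl_batch <- function(x, ...) {
  yr <- attr(x, "year_range")
  cat(sprintf("<fopnl_batch> %d products, years %s-%s, source: %s\n",
              nrow(x), yr[1], yr[2], attr(x, "provenance") %||% "?"))
  NextMethod()
}

#' Remove duplicate product records
#'
#' Products are identified by their unique barcode; repeated barcodes are
#' duplicates and the first-seen record is retained. Distinct package sizes
#' of the same product carry distinct barcodes and are deliberately kept.
#'
#' @param batch A [record_batch()].
#' @return The deduplicated batch; the number of rows dropped is available
#'   as `attr(, "n_removed")` and via [dedup_removed()].
#' @export
dedup_records <- function(batch) {
  stopifnot(inherits(batch, "fopnl_batch"))
  keep <- !duplicated(batch$barcode)
  out <- batch[keep, ]
  attr(out, "provenance") <- attr(batch, "provenance")
  attr(out, "year_range") <- if (nrow(out)) range(out$release_year) else c(NA_integer_, NA_integer_)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' @rdname dedup_records
#' @export
dedup_removed <- function(batch) attr(batch, "n_removed") %||% 0L

#' Read / write product tables
#'
#' CSV (UTF-8, header row) and JSON-lines round-trip of a record batch. The
#' ingredient list is serialized as a single `"; "`-delimited field. Unknown
#' extra columns are preserved. A column map (`dialect`) renames source
#' columns to the canonical schema on read.
#'
#' @param path File path; format chosen by extension (`.csv` vs
#'   `.jsonl`/`.ndjson`).
#' @param dialect Optional named character vector mapping canonical column
#'   names to source column names, e.g. `c(barcode = "UPC")`.
#' @param batch A [record_batch()].
#' @return `read_records()` returns a `fopnl_batch`; `write_records()`
#'   returns `path` invisibly.
#' @export
read_records <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
    df <- tibble::as_tibble(df)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  record_batch(df, provenance = path)
}

#' @rdname read_records
#' @export
write_records <- function(batch, path) {
  stopifnot(inherits(batch, "fopnl_batch"))
  df <- as.data.frame(batch)
  df$ingredients <- vapply(batch$ingredients, function(x) {
    if (is.null(x) || !length(x)) NA_character_ else paste(x, collapse = "; ")
  }, character(1))
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
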