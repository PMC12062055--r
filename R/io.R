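# Sentinel strings treated as a missing rate in long CSV extracts. Registry
# exports mark suppressed cells (small counts) with symbols rather than
# leaving them empty, so all of these parse to NA.
MISSING_SENTINELS <- c("", "NA", "^", "*")

#' Read long county-year incidence records from CSV
#'
#' Reads a long-format extract (one row per county-year) with configurable
#' column names, returning one record per row. Empty cells and the
#' suppression sentinels `""`, `"NA"`, `"^"`, `"*"` parse to a missing rate;
#' negative rates are rejected as data corruption.
#'
#' @param path path to a UTF-8 comma-separated file with a header row.
#' @param fips,year,rate names of the columns holding the county code,
#'   calendar year and age-adjusted rate per 100,000.
#' @return a tibble of records with columns `fips` (5-char, zero-padded),
#'   `year` (integer), `rate` (double, `NA` = missing).
#' @seealso [assemble_panel()] to reshape records into a matrix panel.
#' @export
read_incidence_csv <- function(path, fips = "fips", year = "year", rate = "rate") {
  if (!file.exists(path)) {
    abort_validation(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  for (col in c(fips, year, rate)) {
    if (!col %in% names(raw)) {
      abort_validation(sprintf("mapped column '%s' not found in header (%s)",
                               col, paste(names(raw), collapse = ", ")),
                       class = "dmdcast_schema_error")
    }
  }
  yr_chr <- trimws(raw[[year]])
  yr <- suppressWarnings(as.integer(yr_chr))
  if (anyNA(yr)) {
    bad <- which(is.na(yr))[1]
    abort_validation(sprintf("unparseable year '%s' at data line %d",
                             yr_chr[bad], bad + 1L),
                     class = "dmdcast_parse_error")
  }
  rt_chr <- trimws(raw[[rate]])
  missing <- rt_chr %in% MISSING_SENTINELS
  rt <- rep(NA_real_, length(rt_chr))
  rt[!missing] <- suppressWarnings(as.numeric(rt_chr[!missing]))
  unparsed <- !missing & is.na(rt)
  if (any(unparsed)) {
    bad <- which(unparsed)[1]
    abort_validation(sprintf("unparseable rate '%s' at data line %d",
                             rt_chr[bad], bad + 1L),
                     class = "dmdcast_parse_error")
  }
  if (any(rt < 0, na.rm = TRUE)) {
    bad <- which(rt < 0)[1]
    abort_validation(sprintf("negative rate %s at data line %d (corrupt input)",
                             rt_chr[bad], bad + 1L),
                     class = "dmdcast_parse_error")
  }
  tibble::tibble(fips = pad_fips(raw[[fips]]), year = yr, rate = rt)
}

#' Assemble long records into a wide incidence panel
#'
#' Pivots county-year records into the counties-by-years matrix form, with
#' rows sorted by fips ascending and one column for every consecutive year
#' of `year_range`. County-year pairs absent from the records become missing
#' cells; duplicated pairs must agree on the rate.
#'
#' @param records a data frame with columns `fips`, `year`, `rate`
#'   (as returned by [read_incidence_csv()]).
#' @param year_range length-2 integer `c(min, max)`; default spans the
#'   records' own years.
#' @return an [incidence_panel()] (possibly with missing cells).
#' @export
assemble_panel <- function(records, year_range = NULL) {
  stopifnot(is.data.frame(records), all(c("fips", "year", "rate") %in% names(records)))
  records <- tibble::as_tibble(records)
  records$fips <- pad_fips(records$fips)
  records$year <- as.integer(records$year)
  year_range <- year_range %||% range(records$year)
  years <- seq(as.integer(year_range[1]), as.integer(year_range[2]))
  records <- records[records$year %in% years, , drop = FALSE]
  if (nrow(records) == 0L) {
    abort_validation("no records inside year_range")
  }
  dup <- dplyr::summarise(
    dplyr::group_by(records, .data$fips, .data$year),
    n_rates = dplyr::n_distinct(.data$rate, na.rm = FALSE),
    .groups = "drop"
  )
  conflict <- dup[dup$n_rates > 1L, ]
  if (nrow(conflict) > 0L) {
    pairs <- paste(sprintf("(%s, %d)", conflict$fips, conflict$year), collapse = ", ")
    abort_validation(sprintf("conflicting duplicate records for %s", pairs),
                     class = "dmdcast_integrity_error")
  }
  records <- dplyr::distinct(records, .data$fips, .data$year, .keep_all = TRUE)
  counties <- sort(unique(records$fips))
  values <- matrix(NA_real_, length(counties), length(years),
                   dimnames = list(counties, years))
  values[cbind(match(records$fips, counties), match(records$year, years))] <- records$rate
  incidence_panel(counties, years, values)
}

#' Write and read wide panel CSV
#'
#' The wide dialect has header `fips,<year1>,...,<yearM>` and one row per
#' county; it round-trips through `read_panel_csv()` to an equal panel.
#' Writing requires a complete panel (no missing cells).
#'
#' @param panel a complete `incidence_panel`.
#' @param path output/input file path.
#' @return `write_panel_csv()` returns `path` invisibly; `read_panel_csv()`
#'   returns an [incidence_panel()].
#' @export
write_panel_csv <- function(panel, path) {
  panel <- as_incidence_panel(panel)
  if (nrow(panel) == 0L) {
    abort_validation("refusing to write an empty panel")
  }
  if (anyNA(panel_matrix(panel))) {
    abort_validation("panel has missing cells; run filter_complete() first")
  }
  readr::write_csv(tibble::as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    fips = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  as_incidence_panel(raw)
}
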