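#' Incidence panels
#'
#' An incidence panel is the package's central data container: a wide tibble
#' with a `fips` column (5-character zero-padded county codes, sorted
#' ascending) and one numeric column per calendar year, years strictly
#' consecutive. It holds the counties-by-years rate matrix that dynamic mode
#' decomposition and all comparator forecasters consume. Cells may be `NA`
#' (missing) until [filter_complete()] is applied.
#'
#' @param fips character vector of county codes (padded with [pad_fips()]).
#' @param years integer vector of consecutive calendar years.
#' @param values numeric matrix, `length(fips)` rows by `length(years)`
#'   columns, of age-adjusted rates per 100,000.
#' @return a tibble of class `incidence_panel`.
#' @examples
#' incidence_panel(c("06037", "21001"), 2000:2002,
#'                 matrix(c(40, 41, 42, 90, 91, 92), 2, 3, byrow = TRUE))
#' @export
incidence_panel <- function(fips, years, values) {
  fips <- pad_fips(fips)
  years <- as.integer(years)
  values <- as.matrix(values)
  if (nrow(values) != length(fips) || ncol(values) != length(years)) {
    abort_validation("values must be a length(fips) x length(years) matrix")
  }
  if (length(years) > 1L && any(diff(years) != 1L)) {
    abort_validation("panel years must be strictly consecutive")
  }
  if (anyDuplicated(fips)) {
    abort_validation(sprintf(
      "duplicated fips codes: %s",
      paste(unique(fips[duplicated(fips)]), collapse = ", ")
    ))
  }
  ord <- order(fips)
  out <- tibble::tibble(fips = fips[ord])
  vals <- values[ord, , drop = FALSE]
  for (j in seq_along(years)) out[[as.character(years[j])]] <- as.numeric(vals[, j])
  class(out) <- c("incidence_panel", class(out))
  out
}

as_incidence_panel <- function(x) {
  if (inherits(x, "incidence_panel")) return(x)
  if (!is.data.frame(x) || !"fips" %in% names(x)) {
    abort_validation("expected an incidence_panel or a wide data frame with a 'fips' column")
  }
  yr_cols <- setdiff(names(x), "fips")
  if (!all(grepl("^[0-9]{4}$", yr_cols))) {
    abort_validation("wide panel columns other than 'fips' must be 4-digit years")
  }
  incidence_panel(x$fips, as.integer(yr_cols),
                  as.matrix(x[, yr_cols, drop = FALSE]))
}

#' @describeIn incidence_panel the panel's calendar years, as integers.
#' @param panel an `incidence_panel`.
#' @export
panel_years <- function(panel) {
  as.integer(setdiff(names(panel), "fips"))
}

#' @describeIn incidence_panel the counties-by-years rate matrix
#'   (rownames = fips, colnames = years).
#' @export
panel_matrix <- function(panel) {
  panel <- as_incidence_panel(panel)
  yrs <- panel_years(panel)
  m <- as.matrix(panel[, as.character(yrs), drop = FALSE])
  rownames(m) <- panel$fips
  m
}

#' Keep only counties observed in every year
#'
#' Complete-case filtering at the county level: a county with any missing
#' year is dropped entirely (no imputation). The removed codes are recorded
#' in the `dropped` attribute, readable with [dropped_counties()].
#'
#' @param panel an `incidence_panel`, possibly with `NA` cells.
#' @return the filtered panel; `attr(., "dropped")` lists removed fips codes
#'   in original row order.
#' @examples
#' p <- incidence_panel(c("06037", "21001"), 2000:2001,
#'                      matrix(c(40, NA, 90, 91), 2, 2, byrow = TRUE))
#' filter_complete(p)
#' dropped_counties(filter_complete(p))
#' @export
filter_complete <- function(panel) {
  panel <- as_incidence_panel(panel)
  m <- panel_matrix(panel)
  keep <- stats::complete.cases(m)
  if (!any(keep)) {
    abort_validation("all counties have missing years; empty panel after filtering",
                     class = "dmdcast_empty_panel_error")
  }
  out <- panel[keep, , drop = FALSE]
  class(out) <- c("incidence_panel", setdiff(class(out), "incidence_panel"))
  attr(out, "dropped") <- panel$fips[!keep]
  out
}

#' @describeIn filter_complete fips codes removed by the last
#'   `filter_complete()` call (empty character vector if none).
#' @export
dropped_counties <- function(panel) {
  attr(panel, "dropped") %||% character()
}

#' Tidy an incidence panel into long county-year records
#'
#' @param x an `incidence_panel`.
#' @param ... unused.
#' @return a tibble with columns `fips`, `year`, `rate` (one row per
#'   county-year; `rate` may be `NA`).
#' @export
tidy.incidence_panel <- function(x, ...) {
  x <- as_incidence_panel(x)
  out <- tidyr::pivot_longer(tibble::as_tibble(x), -"fips",
                             names_to = "year", values_to = "rate")
  out$year <- as.integer(out$year)
  dplyr::arrange(out, .data$fips, .data$year)
}

#' @export
print.incidence_panel <- function(x, ...) {
  yrs <- panel_years(x)
  cat(sprintf("<incidence_panel> %d counties x %d years (%d-%d)\n",
              nrow(x), length(yrs), min(yrs), max(yrs)))
  n_missing <- sum(is.na(panel_matrix(x)))
  if (n_missing > 0) cat(sprintf("  %d missing cells\n", n_missing))
  NextMethod()
  invisible(x)
}
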