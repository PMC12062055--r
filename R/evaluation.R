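#' Root mean squared error
#'
#' @param pred,actual aligned numeric vectors without missing entries.
#' @return `sqrt(mean((pred - actual)^2))`.
#' @export
rmse <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    abort_validation("pred and actual differ in length",
                     class = "dmdcast_alignment_error")
  }
  if (length(pred) < 1L) abort_validation("need at least one pair")
  if (anyNA(pred) || anyNA(actual)) {
    abort_validation("missing entries in pred/actual")
  }
  sqrt(mean((pred - actual)^2))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tied observations receive the average
#' of the ranks they span). Constant input — zero rank variance — is an
#' error rather than a silent 0: a constant forecaster upstream is a bug
#' worth surfacing.
#'
#' @param pred,actual aligned numeric vectors, length >= 2, no missing
#'   entries.
#' @return correlation in `[-1, 1]`.
#' @export
spearman <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    abort_validation("pred and actual differ in length",
                     class = "dmdcast_alignment_error")
  }
  if (length(pred) < 2L) abort_validation("need at least two pairs")
  if (anyNA(pred) || anyNA(actual)) {
    abort_validation("missing entries in pred/actual")
  }
  if (var(rank(pred)) == 0 || var(rank(actual)) == 0) {
    abort_validation("rank variance is zero; Spearman correlation undefined",
                     class = "dmdcast_undefined_correlation_error")
  }
  cor(pred, actual, method = "spearman")
}

#' Score every model's forecasts against the held-out year
#'
#' Builds the benchmark comparison report: one row per model with its RMSE
#' and Spearman rank correlation against the actual rates. Models with any
#' missing prediction are excluded with a warning.
#'
#' @param forecasts a [forecast_all()] result (or any tibble with `fips`,
#'   optional `actual`, and one numeric column per model).
#' @param actual held-out rates aligned to the forecast rows; defaults to
#'   the `actual` column.
#' @param sort_by `"rmse"` (ascending, default) or `"model"` (column
#'   order).
#' @return a tibble of class `evaluation_report` with columns `model`,
#'   `rmse`, `spearman`, `n`.
#' @export
evaluate_models <- function(forecasts, actual = NULL, sort_by = c("rmse", "model")) {
  sort_by <- match.arg(sort_by)
  stopifnot(is.data.frame(forecasts))
  actual <- actual %||% forecasts[["actual"]]
  if (is.null(actual)) {
    abort_validation("no actual values: pass `actual` or include an 'actual' column")
  }
  if (length(actual) != nrow(forecasts)) {
    abort_validation("actual length must match forecast rows",
                     class = "dmdcast_alignment_error")
  }
  model_cols <- setdiff(names(forecasts), c("fips", "actual"))
  if (length(model_cols) == 0L) abort_validation("no model columns to score")
  rows <- purrr::map(model_cols, function(mod) {
    pred <- forecasts[[mod]]
    if (anyNA(pred)) {
      warn(sprintf("model '%s' has missing predictions; excluded from report", mod))
      return(NULL)
    }
    tibble::tibble(model = mod, rmse = rmse(pred, actual),
                   spearman = spearman(pred, actual), n = length(pred))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort_runtime("no scorable models")
  if (sort_by == "rmse") out <- dplyr::arrange(out, .data$rmse)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Long predicted-vs-actual table for comparison plots
#'
#' Pivots a forecast table into tidy long format — one row per county and
#' model — the x-y data behind predicted-versus-actual overlays.
#'
#' @param forecasts a [forecast_all()] result with an `actual` column.
#' @param sort_by_actual order counties by ascending actual rate before
#'   indexing (default `FALSE` keeps panel order).
#' @return a tibble with columns `county_index`, `fips`, `actual`, `model`,
#'   `predicted`.
#' @export
comparison_table <- function(forecasts, sort_by_actual = FALSE) {
  stopifnot(is.data.frame(forecasts), "actual" %in% names(forecasts))
  wide <- tibble::as_tibble(forecasts)
  if (sort_by_actual) wide <- dplyr::arrange(wide, .data$actual)
  wide$county_index <- seq_len(nrow(wide))
  out <- tidyr::pivot_longer(wide, -c("county_index", "fips", "actual"),
                             names_to = "model", values_to = "predicted")
  dplyr::select(out, "county_index", "fips", "actual", "model", "predicted")
}
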