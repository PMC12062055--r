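# Classed conditions: validation errors (bad inputs/config) vs runtime errors
# (model/computation failures). The CLI maps these to exit codes 1 and 2.

abort_validation <- function(message, class = character(), ...) {
  abort(message, class = c(class, "dmdcast_validation_error", "dmdcast_error"), ...)
}

abort_runtime <- function(message, class = character(), ...) {
  abort(message, class = c(class, "dmdcast_runtime_error", "dmdcast_error"), ...)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Zero-pad county FIPS codes to five characters
#'
#' @param x character or numeric vector of FIPS codes (1-5 digits).
#' @return character vector of 5-character zero-padded codes.
#' @examples
#' pad_fips(c("6037", 21001))
#' @export
pad_fips <- function(x) {
  x <- trimws(as.character(x))
  bad <- !grepl("^[0-9]{1,5}$", x)
  if (any(bad)) {
    abort_validation(sprintf(
      "invalid FIPS code(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ), class = "dmdcast_fips_error")
  }
  formatC(as.integer(x), width = 5, flag = "0", format = "d")
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}
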