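#' Build the shifted snapshot pair for DMD
#'
#' Restricts the panel to the training years and splits its matrix into the
#' two time-shifted snapshot matrices `X1` (snapshots 1..m-1) and `X2`
#' (snapshots 2..m) whose linear relation \eqn{X_2 \approx A X_1} DMD
#' identifies.
#'
#' @param panel a complete [incidence_panel()].
#' @param train_years integer vector of consecutive years to train on
#'   (default: all panel years).
#' @return a list of class `snapshot_pair` with elements `X1`, `X2`
#'   (n x (m-1) matrices), `m` (snapshot count), `fips`, `years`.
#' @export
build_snapshots <- function(panel, train_years = NULL) {
  panel <- as_incidence_panel(panel)
  yrs <- panel_years(panel)
  train_years <- as.integer(train_years %||% yrs)
  if (!all(train_years %in% yrs)) {
    abort_validation("train_years must be a subset of panel years")
  }
  if (length(train_years) > 1L && any(diff(train_years) != 1L)) {
    abort_validation("train_years must be consecutive")
  }
  m <- length(train_years)
  if (m < 2L) {
    abort_validation("need at least 2 snapshots to form a shifted pair",
                     class = "dmdcast_snapshot_error")
  }
  X <- panel_matrix(panel)[, as.character(train_years), drop = FALSE]
  if (anyNA(X)) {
    abort_validation("training window contains missing cells; run filter_complete() first")
  }
  pair <- list(X1 = X[, -m, drop = FALSE], X2 = X[, -1, drop = FALSE],
               m = m, fips = panel$fips, years = train_years)
  # shift consistency is structural here, but assert the contract anyway
  if (m > 2L && !identical(pair$X1[, -1, drop = FALSE],
                           pair$X2[, -(m - 1), drop = FALSE])) {
    abort_runtime("snapshot pair violates shift consistency")
  }
  structure(pair, class = "snapshot_pair")
}

numerical_rank <- function(d, n, p) {
  if (length(d) == 0L || d[1] <= 0) return(0L)
  sum(d > max(n, p) * .Machine$double.eps * d[1])
}

#' Fit an exact dynamic mode decomposition
#'
#' Exact DMD of the snapshot pair at a chosen rank: reduced SVD
#' \eqn{X_1 \approx U \Sigma V^*}, reduced operator
#' \eqn{\tilde A = U^* X_2 V \Sigma^{-1}} (an r x r projection of the full
#' propagator \eqn{A = X_2 V \Sigma^{-1} U^*}, never materialized),
#' eigendecomposition \eqn{\tilde A W = W \Lambda}, exact modes
#' \eqn{\Phi = X_2 V \Sigma^{-1} W}, and amplitudes `b` solving the least
#' squares problem \eqn{\Phi b \approx x_1} against the first snapshot.
#' Modes are rescaled to unit Euclidean norm with the scale absorbed into
#' `b`, so per-county mode magnitudes are comparable across runs.
#' Eigenvalues are ordered by modulus descending, ties by phase ascending.
#'
#' @param snapshots a `snapshot_pair` from [build_snapshots()], or a
#'   complete panel (all years then form the training window).
#' @param rank truncation rank `r`, or `"full"` for the numerical rank of
#'   `X1` (singular values above `max(n, m-1) * eps * sigma_1`).
#' @return an object of class `dmd`: fields `rank`, `U`, `S`, `V`,
#'   `A_tilde`, `eigenvalues`, `W`, `modes`, `amplitudes`, `singular_values`
#'   (all of `X1`), `numerical_rank`, `m`, `n`, `fips`, `years`.
#' @examples
#' p <- incidence_panel("21001", 2000:2003, matrix(c(100, 90, 81, 72.9), 1))
#' fit <- dmd_fit(build_snapshots(p), rank = 1)
#' fit$eigenvalues          # 0.9
#' predict(fit, k = 5)      # 65.61
#' @export
dmd_fit <- function(snapshots, rank = "full") {
  if (inherits(snapshots, "incidence_panel") || is.data.frame(snapshots)) {
    snapshots <- build_snapshots(snapshots)
  }
  stopifnot(inherits(snapshots, "snapshot_pair"))
  X1 <- snapshots$X1
  X2 <- snapshots$X2
  n <- nrow(X1)
  p <- ncol(X1)

  sv <- svd(X1)
  nr <- numerical_rank(sv$d, n, p)
  if (nr == 0L) {
    abort_validation("X1 is a zero matrix; DMD is undefined",
                     class = "dmdcast_degenerate_error")
  }
  if (identical(rank, "full")) {
    r <- nr
  } else {
    r <- as.integer(rank)
    if (is.na(r) || r < 1L || r > nr) {
      abort_validation(sprintf(
        "requested rank %s outside [1, %d] (numerical rank of X1)",
        as.character(rank), nr
      ), class = "dmdcast_rank_error")
    }
  }

  U <- sv$u[, seq_len(r), drop = FALSE]
  S <- sv$d[seq_len(r)]
  V <- sv$v[, seq_len(r), drop = FALSE]

  X2VSi <- X2 %*% sweep(V, 2, S, `/`)        # X2 V Sigma^{-1}, reused for modes
  A_tilde <- crossprod(U, X2VSi)             # U* X2 V Sigma^{-1}

  eig <- eigen(A_tilde)
  lambda <- as.complex(eig$values)
  W <- matrix(as.complex(eig$vectors), r, r)
  ord <- order(-Mod(lambda), Arg(lambda))
  lambda <- lambda[ord]
  W <- W[, ord, drop = FALSE]

  Phi <- X2VSi %*% W                          # exact DMD modes
  norms <- sqrt(colSums(Mod(Phi)^2))
  norms[norms == 0] <- 1
  Phi <- sweep(Phi, 2, norms, `/`)

  b <- drop(complex_lstsq(Phi, X1[, 1]))

  structure(list(
    rank = r, U = U, S = S, V = V, A_tilde = A_tilde,
    eigenvalues = lambda, W = W, modes = Phi, amplitudes = b,
    singular_values = sv$d, numerical_rank = nr,
    m = snapshots$m, n = n, fips = snapshots$fips, years = snapshots$years
  ), class = "dmd")
}

# minimum-norm least squares for complex systems via the complex SVD
complex_lstsq <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (!any(keep)) return(complex(real = rep(0, ncol(A))))
  rhs <- Conj(t(sv$u[, keep, drop = FALSE])) %*% as.complex(y)
  sv$v[, keep, drop = FALSE] %*% (rhs / sv$d[keep])
}

#' Predict a snapshot from a fitted DMD model
#'
#' Evaluates the modal expansion \eqn{x_k = \Phi \Lambda^{k-1} b} at step
#' `k` and returns its real part (incidence rates are real; for
#' conjugate-closed spectra the imaginary residual is at rounding level).
#' Step `k = 1` is the first training year; `k = m + 1` is the one-step
#' forecast beyond the training window.
#'
#' @param object a fitted `dmd` model.
#' @param k step index, integer `>= 1`.
#' @param ... unused.
#' @return a named real vector of per-county rates (names = fips).
#' @export
predict.dmd <- function(object, k = object$m + 1L, ...) {
  if (length(k) != 1L || !is_wholenumber(k) || k < 1) {
    abort_validation("step index k must be a single integer >= 1")
  }
  x <- object$modes %*% (object$eigenvalues^(k - 1) * drop(object$amplitudes))
  setNames(Re(drop(x)), object$fips)
}

#' Rank sweep: forecast error and retained energy per truncation rank
#'
#' For each candidate rank, fits DMD on the snapshot pair, forecasts the
#' step after the last training snapshot, and scores it against `holdout`;
#' the energy ratio is the fraction of squared singular-value mass of `X1`
#' retained at that rank, \eqn{\sum_{i \le r} \sigma_i^2 / \sum_i \sigma_i^2}.
#'
#' @param snapshots a `snapshot_pair`.
#' @param holdout real vector of observed rates for the held-out year,
#'   aligned with the snapshot county order.
#' @param ranks integer vector of ranks (default `1:numerical_rank`).
#' @return a tibble of class `dmd_rank_sweep` with columns `rank`, `rmse`,
#'   `energy_ratio`.
#' @export
rank_sweep <- function(snapshots, holdout, ranks = NULL) {
  stopifnot(inherits(snapshots, "snapshot_pair"))
  if (length(holdout) != nrow(snapshots$X1)) {
    abort_validation("holdout length must equal the county count")
  }
  d <- svd(snapshots$X1, nu = 0, nv = 0)$d
  nr <- numerical_rank(d, nrow(snapshots$X1), ncol(snapshots$X1))
  ranks <- as.integer(ranks %||% seq_len(nr))
  energy <- cumsum(d^2) / sum(d^2)
  rows <- purrr::map(ranks, function(r) {
    fit <- tryCatch(dmd_fit(snapshots, rank = r), error = function(e) {
      abort_validation(sprintf("rank %d: %s", r, conditionMessage(e)),
                       class = "dmdcast_rank_error", parent = e)
    })
    tibble::tibble(rank = r,
                   rmse = rmse(predict(fit, k = snapshots$m + 1L), holdout),
                   energy_ratio = energy[r])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dmd_rank_sweep", class(out))
  out
}

#' Eigenvalue spectrum diagnostics
#'
#' One row per retained DMD eigenvalue with its Cartesian coordinates,
#' modulus, oscillation frequency `|arg(lambda)|` (radians per year), growth
#' rate `ln|lambda|` (per year), and whether it lies strictly inside the
#' unit circle (a decaying mode). `|lambda| = 1` counts as outside, and
#' moduli within `1e-8` of the circle are classed as boundary rather than
#' inside, so exactly-neutral dynamics are not misread as decaying through
#' rounding.
#'
#' @param model a fitted `dmd`.
#' @return a tibble with columns `re`, `im`, `modulus`, `frequency`,
#'   `growth`, `inside_unit_circle`.
#' @export
eigen_spectrum <- function(model) {
  stopifnot(inherits(model, "dmd"))
  l <- model$eigenvalues
  tibble::tibble(
    re = Re(l), im = Im(l), modulus = Mod(l),
    frequency = abs(Arg(l)), growth = log(Mod(l)),
    inside_unit_circle = Mod(l) < 1 - 1e-8
  )
}

#' Per-county magnitude of the dominant steady mode
#'
#' Selects, among eigenvalues with near-zero frequency
#' (`|arg(lambda)| < angular_tol`), the one with the largest amplitude at
#' the last training step, \eqn{|b_j| |\lambda_j|^{m-1}}, and reports each
#' county's loading magnitude \eqn{|\phi_{j,i}|} — the join-ready table
#' behind a dominant-mode choropleth.
#'
#' @param model a fitted `dmd`.
#' @param angular_tol angular tolerance in radians for "zero frequency"
#'   (default `1e-6`).
#' @return a tibble with columns `fips`, `magnitude`; attributes `lambda`
#'   (the selected eigenvalue) and `mode_index`.
#' @export
dominant_mode_table <- function(model, angular_tol = 1e-6) {
  stopifnot(inherits(model, "dmd"))
  freq <- abs(Arg(model$eigenvalues))
  candidates <- which(freq < angular_tol)
  if (length(candidates) == 0L) {
    abort_validation(sprintf(
      paste0("no eigenvalue with |arg(lambda)| < %g; the retained spectrum ",
             "has no steady mode (consider a looser angular_tol)"), angular_tol
    ), class = "dmdcast_no_steady_mode_error")
  }
  score <- Mod(model$amplitudes[candidates]) *
    Mod(model$eigenvalues[candidates])^(model$m - 1)
  j <- candidates[which.max(score)]
  out <- tibble::tibble(fips = model$fips, magnitude = Mod(model$modes[, j]))
  attr(out, "lambda") <- model$eigenvalues[j]
  attr(out, "mode_index") <- j
  out
}

#' @export
print.dmd <- function(x, ...) {
  cat(sprintf("<dmd> rank %d fit of %d counties x %d snapshots (years %d-%d)\n",
              x$rank, x$n, x$m, min(x$years), max(x$years)))
  cat(sprintf("  numerical rank of X1: %d\n", x$numerical_rank))
  cat("  leading eigenvalues:",
      paste(format(head(x$eigenvalues, 4), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname eigen_spectrum
#' @param x a fitted `dmd`.
#' @param ... unused.
#' @export
tidy.dmd <- function(x, ...) eigen_spectrum(x)

#' One-row summary of a DMD fit
#'
#' @param x a fitted `dmd`.
#' @param ... unused.
#' @return a one-row tibble: `rank`, `n`, `m`, `numerical_rank`,
#'   `energy_ratio` (at the fitted rank), `max_modulus`,
#'   `frac_inside_unit_circle`.
#' @export
glance.dmd <- function(x, ...) {
  d2 <- x$singular_values^2
  tibble::tibble(
    rank = x$rank, n = x$n, m = x$m, numerical_rank = x$numerical_rank,
    energy_ratio = sum(d2[seq_len(x$rank)]) / sum(d2),
    max_modulus = max(Mod(x$eigenvalues)),
    frac_inside_unit_circle = mean(Mod(x$eigenvalues) < 1 - 1e-8)
  )
}

#' Serialize a DMD model to a portable JSON bundle
#'
#' Matrices are stored as nested row-major arrays; complex quantities as
#' parallel `re`/`im` arrays. [read_dmd_json()] restores an equivalent
#' model.
#'
#' @param model a fitted `dmd`.
#' @param path output/input path.
#' @return `path` invisibly / the restored `dmd` object.
#' @export
write_dmd_json <- function(model, path) {
  stopifnot(inherits(model, "dmd"))
  cplx <- function(z) list(re = Re(z), im = Im(z))
  payload <- list(
    rank = model$rank, n = model$n, m = model$m,
    numerical_rank = model$numerical_rank,
    fips = model$fips, years = model$years,
    U = model$U, S = model$S, V = model$V, A_tilde = model$A_tilde,
    singular_values = model$singular_values,
    eigenvalues = cplx(model$eigenvalues),
    W = cplx(model$W), modes = cplx(model$modes),
    amplitudes = cplx(drop(model$amplitudes))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_dmd_json
#' @export
read_dmd_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  uncplx <- function(z) complex(real = unlist(z$re), imaginary = unlist(z$im))
  r <- p$rank
  structure(list(
    rank = r, U = matrix(p$U, p$n, r), S = p$S, V = matrix(p$V, ncol = r),
    A_tilde = matrix(p$A_tilde, r, r),
    eigenvalues = uncplx(p$eigenvalues),
    W = matrix(uncplx(p$W), r, r),
    modes = matrix(uncplx(p$modes), p$n, r),
    amplitudes = uncplx(p$amplitudes),
    singular_values = p$singular_values, numerical_rank = p$numerical_rank,
    m = p$m, n = p$n, fips = p$fips, years = p$years
  ), class = "dmd")
}
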