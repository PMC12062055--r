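#' Configuration for the synthetic low-rank panel generator
#'
#' The generator simulates registry-like county-by-year incidence panels
#' from a known low-rank linear dynamical system: the noise-free state at
#' snapshot k is \eqn{x_k = \sum_j \phi_j \lambda_j^{k-1} b_j}, the same
#' modal form a DMD fit predicts with, so true eigenvalues, modes and
#' amplitudes are retained for parameter-recovery tests. The default
#' spectrum is one slowly decaying real mode (the secular decline of rates)
#' plus one oscillatory conjugate pair.
#'
#' @param n_counties,n_years panel dimensions (default 1000 counties, 22
#'   annual snapshots).
#' @param eigenvalues complex vector of true eigenvalues; non-real entries
#'   must come in conjugate pairs. Default `c(0.97, 0.9*exp(0.6i), 0.9*exp(-0.6i))`.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian
#'   observation noise, in rate units per 100,000 (default 2).
#' @param missing_fraction fraction in `[0, 1)` of counties given at least
#'   one missing year (default 0), see [inject_missing()].
#' @param seed integer RNG seed; the panel is bit-identical given
#'   `(config, seed)`.
#' @param n_blocks number of contiguous pseudo-state blocks encoded in the
#'   first two FIPS digits.
#' @param high_block 2-digit block code whose counties get an inflated
#'   dominant-mode loading (the high-incidence cluster analog).
#' @param block_multiplier loading multiplier for `high_block` (default 3).
#' @param level approximate mean rate per 100,000 carried by the dominant
#'   mode at the first snapshot (default 60, a realistic age-adjusted lung
#'   cancer incidence scale).
#' @param osc_level approximate per-county amplitude of each secondary mode,
#'   in rate units (default 6).
#' @param baseline additive constant offset in rate units (default 0). A
#'   non-zero baseline is a constant component and raises the noise-free
#'   numerical rank by one; defaults keep rates positive through the
#'   all-positive dominant mode instead, preserving exact rank.
#' @param modes optional explicit n x r complex mode matrix (columns used
#'   as-is, no normalization); overrides the random construction.
#' @param amplitudes optional explicit complex r-vector of amplitudes.
#' @param clip_negative clamp observed rates at 0 after noise (default
#'   `FALSE`; clipping breaks linearity and spoils recovery tests).
#' @param start_year first calendar year (default 2000).
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_counties = 1000, n_years = 22,
                             eigenvalues = c(0.97, 0.9 * exp(0.6i), 0.9 * exp(-0.6i)),
                             noise_sd = 2, missing_fraction = 0, seed = 7,
                             n_blocks = 10, high_block = "21",
                             block_multiplier = 3, level = 60, osc_level = 6,
                             baseline = 0, modes = NULL, amplitudes = NULL,
                             clip_negative = FALSE, start_year = 2000) {
  eigenvalues <- as.complex(eigenvalues)
  r_true <- length(eigenvalues)
  cfg <- list(
    n_counties = as.integer(n_counties), n_years = as.integer(n_years),
    eigenvalues = eigenvalues, r_true = r_true, noise_sd = noise_sd,
    missing_fraction = missing_fraction, seed = as.integer(seed),
    n_blocks = as.integer(n_blocks), high_block = high_block,
    block_multiplier = block_multiplier, level = level,
    osc_level = osc_level, baseline = baseline,
    modes = modes, amplitudes = amplitudes,
    clip_negative = isTRUE(clip_negative), start_year = as.integer(start_year)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_counties < 1L || cfg$n_years < 2L) {
    abort_validation("need n_counties >= 1 and n_years >= 2")
  }
  if (cfg$r_true < 1L || cfg$r_true > min(cfg$n_counties, cfg$n_years - 1L)) {
    abort_validation("r_true must satisfy 1 <= r_true <= min(n_counties, n_years - 1)")
  }
  if (any(Mod(cfg$eigenvalues) > 1.05)) {
    abort_validation("eigenvalue magnitudes must not exceed 1.05")
  }
  if (!conjugate_closed(cfg$eigenvalues)) {
    abort_validation("non-real eigenvalues must occur in conjugate pairs")
  }
  if (cfg$noise_sd < 0) abort_validation("noise_sd must be >= 0")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    abort_validation("missing_fraction must lie in [0, 1)")
  }
  if (!is.null(cfg$modes)) {
    m <- as.matrix(cfg$modes)
    if (nrow(m) != cfg$n_counties || ncol(m) != cfg$r_true) {
      abort_validation("modes must be n_counties x length(eigenvalues)")
    }
  }
  if (!is.null(cfg$amplitudes) && length(cfg$amplitudes) != cfg$r_true) {
    abort_validation("amplitudes must have one entry per eigenvalue")
  }
  invisible(cfg)
}

# multiset of non-real values closed under conjugation (within tolerance)
conjugate_closed <- function(lambda, tol = 1e-10) {
  cplx <- lambda[abs(Im(lambda)) > tol]
  if (length(cplx) == 0L) return(TRUE)
  remaining <- cplx
  while (length(remaining) > 0L) {
    target <- Conj(remaining[1])
    j <- which(Mod(remaining[-1] - target) < tol * max(1, Mod(target)))[1]
    if (is.na(j)) return(FALSE)
    remaining <- remaining[-c(1L, j + 1L)]
  }
  TRUE
}

# Synthetic 5-digit FIPS: first 2 digits = block (pseudo-state), last 3 the
# county index within the block. Contiguous blocks, sizes as even as possible.
synthetic_fips <- function(n, n_blocks, high_block) {
  pool <- sprintf("%02d", setdiff(1:56, as.integer(high_block)))
  codes <- c(high_block, pool)[seq_len(n_blocks)]
  sizes <- rep(n %/% n_blocks, n_blocks)
  if (n %% n_blocks > 0) sizes[seq_len(n %% n_blocks)] <- sizes[seq_len(n %% n_blocks)] + 1L
  if (any(sizes > 999L)) abort_validation("block size exceeds 999 counties; increase n_blocks")
  block <- rep(codes, sizes)
  within <- unlist(lapply(sizes, seq_len))
  sprintf("%s%03d", block, within)
}

#' Generate a synthetic incidence panel with known ground truth
#'
#' Runs the modal form forward for `n_years` snapshots, adds observation
#' noise, and returns the panel together with a `synthetic_truth` record of
#' the generating eigenvalues, unit-norm modes, amplitudes and block
#' assignment (retrievable with [synthetic_truth()]). The dominant real mode
#' has all-positive county loadings, inflated by `block_multiplier` on the
#' `high_block` counties, so rates are positive and spatially clustered.
#'
#' @param config a [generator_config()].
#' @return an [incidence_panel()]; attributes `truth` (class
#'   `synthetic_truth`) and, when `missing_fraction > 0`, `missing_log`.
#' @examples
#' cfg <- generator_config(n_counties = 20, n_years = 8, noise_sd = 0, seed = 1)
#' panel <- generate_panel(cfg)
#' synthetic_truth(panel)$eigenvalues
#' @export
generate_panel <- function(config) {
  validate_generator_config(config)
  n <- config$n_counties
  m <- config$n_years
  lambda <- config$eigenvalues
  r <- config$r_true

  out <- with_seed(config$seed, {
    fips <- synthetic_fips(n, config$n_blocks, config$high_block)
    ord <- order(fips)

    Phi <- config$modes
    b <- config$amplitudes
    if (is.null(Phi)) {
      Phi <- matrix(0i, n, r)
      real_idx <- which(abs(Im(lambda)) <= 1e-10)
      dominant <- if (length(real_idx)) real_idx[which.max(Mod(lambda[real_idx]))] else NA_integer_
      done <- logical(r)
      for (j in seq_len(r)) {
        if (done[j]) next
        if (abs(Im(lambda[j])) <= 1e-10) {
          if (!is.na(dominant) && j == dominant) {
            w <- runif(n, 0.7, 1.3)
            w[substr(fips, 1, 2) == config$high_block] <-
              w[substr(fips, 1, 2) == config$high_block] * config$block_multiplier
          } else {
            w <- rnorm(n)
          }
          Phi[, j] <- as.complex(w / sqrt(sum(w^2)))
          done[j] <- TRUE
        } else {
          k <- which(!done & Mod(lambda - Conj(lambda[j])) < 1e-10 * max(1, Mod(lambda[j])))
          k <- setdiff(k, j)[1]
          z <- complex(real = rnorm(n), imaginary = rnorm(n))
          z <- z / sqrt(sum(Mod(z)^2))
          Phi[, j] <- z
          Phi[, k] <- Conj(z)
          done[c(j, k)] <- TRUE
        }
      }
      if (is.null(b)) {
        b <- complex(real = rep(0, r))
        done <- logical(r)
        for (j in seq_len(r)) {
          if (done[j]) next
          if (abs(Im(lambda[j])) <= 1e-10) {
            b[j] <- if (!is.na(dominant) && j == dominant) {
              config$level * sqrt(n)
            } else {
              config$osc_level * sqrt(n)
            }
            done[j] <- TRUE
          } else {
            k <- setdiff(which(!done & Mod(lambda - Conj(lambda[j])) < 1e-10), j)[1]
            amp <- config$osc_level * sqrt(n) / 2 * exp(1i * runif(1, 0, 2 * pi))
            b[j] <- amp
            b[k] <- Conj(amp)
            done[c(j, k)] <- TRUE
          }
        }
      }
    } else {
      Phi <- matrix(as.complex(Phi), n, r)
      if (is.null(b)) abort_validation("amplitudes must accompany explicit modes")
    }
    b <- as.complex(b)

    # x_k = Re(Phi diag(lambda^{k-1}) b); conjugate pairing keeps Im ~ 0
    powers <- outer(lambda, 0:(m - 1), `^`)          # r x m
    states <- Phi %*% (powers * b)                    # n x m complex
    scale <- max(Mod(states), 1)
    if (max(abs(Im(states))) > 1e-8 * scale) {
      abort_validation("generating system is not conjugate-closed: states are not real")
    }
    values <- Re(states) + config$baseline
    if (config$noise_sd > 0) {
      values <- values + matrix(rnorm(n * m, sd = config$noise_sd), n, m)
    }
    if (config$clip_negative) values <- pmax(values, 0)

    truth <- structure(list(
      eigenvalues = lambda,
      modes = Phi[ord, , drop = FALSE],
      amplitudes = b,
      noise_sd = config$noise_sd,
      seed = config$seed,
      baseline = config$baseline,
      block_assignment = tibble::tibble(
        fips = sort(fips), block = substr(sort(fips), 1, 2)
      ),
      high_block = config$high_block
    ), class = "synthetic_truth")

    years <- seq(config$start_year, length.out = m)
    panel <- incidence_panel(fips, years, values)
    attr(panel, "truth") <- truth
    panel
  })

  if (config$missing_fraction > 0) {
    out <- inject_missing(out, config$missing_fraction, config$seed + 1L)
  }
  out
}

#' @describeIn generate_panel retrieve the `synthetic_truth` attribute
#'   (generating eigenvalues, modes, amplitudes, noise level, blocks).
#' @param panel a panel produced by `generate_panel()`.
#' @export
synthetic_truth <- function(panel) {
  attr(panel, "truth")
}

#' Inject missing years into a fraction of counties
#'
#' Marks `floor(fraction * n)` counties, chosen reproducibly by `seed`, as
#' incomplete by blanking one to three of their years — emulating registry
#' extracts where some counties lack usable data, so that the
#' [filter_complete()] rule is exercised end-to-end.
#'
#' @param panel an `incidence_panel`.
#' @param fraction fraction of counties to affect, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return the panel with `NA` cells; `attr(., "missing_log")` lists the
#'   affected fips codes (sorted).
#' @export
inject_missing <- function(panel, fraction, seed) {
  panel <- as_incidence_panel(panel)
  if (fraction < 0 || fraction >= 1) {
    abort_validation("fraction must lie in [0, 1)")
  }
  n <- nrow(panel)
  k <- floor(fraction * n)
  truth <- attr(panel, "truth")
  if (k == 0L) {
    attr(panel, "missing_log") <- character()
    attr(panel, "truth") <- truth
    return(panel)
  }
  yrs <- as.character(panel_years(panel))
  out <- with_seed(seed, {
    rows <- sort(sample.int(n, k))
    for (i in rows) {
      n_gone <- sample.int(min(3L, length(yrs)), 1L)
      gone <- sample(yrs, n_gone)
      for (g in gone) panel[[g]][i] <- NA_real_
    }
    attr(panel, "missing_log") <- sort(panel$fips[rows])
    panel
  })
  attr(out, "truth") <- truth
  out
}

#' @describeIn inject_missing fips codes blanked by the last injection.
#' @export
missing_log <- function(panel) {
  attr(panel, "missing_log") %||% character()
}

#' Serialize synthetic ground truth to a JSON sidecar
#'
#' Complex quantities are written as `[re, im]` pairs; modes as parallel
#' real/imaginary arrays keyed by county order.
#'
#' @param truth a `synthetic_truth` (from [synthetic_truth()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- list(
    eigenvalues = lapply(truth$eigenvalues, function(z) c(Re(z), Im(z))),
    amplitudes = lapply(truth$amplitudes, function(z) c(Re(z), Im(z))),
    modes_re = unname(as.data.frame(Re(truth$modes))),
    modes_im = unname(as.data.frame(Im(truth$modes))),
    noise_sd = truth$noise_sd,
    baseline = truth$baseline,
    seed = truth$seed,
    high_block = truth$high_block,
    block_assignment = truth$block_assignment
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
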