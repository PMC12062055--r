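# Independent oracles and small fixtures shared across the suite. Each
# oracle is deliberately naive (dense pseudoinverse, elementwise loops,
# explicit mid-ranks) and shares no code with the implementation it checks.

write_tmp_csv <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}

# ramp panel: county i follows a_i + d_i * t exactly
ramp_panel <- function(n = 30, m = 10, seed = 1, start_year = 2000) {
  set.seed(seed)
  a <- runif(n, 40, 90)
  d <- runif(n, -2, 2)
  vals <- outer(a, rep(1, m)) + outer(d, seq_len(m))
  incidence_panel(sprintf("%05d", seq_len(n)), start_year + 0:(m - 1), vals)
}

random_panel <- function(n, m, seed, start_year = 2000) {
  set.seed(seed)
  incidence_panel(sprintf("%05d", seq_len(n)), start_year + 0:(m - 1),
                  matrix(abs(rnorm(n * m, 50, 10)), n, m))
}

# dense brute-force DMD oracle: eigenvalues of A = X2 %*% pinv(X1), the
# pseudoinverse computed by MASS::ginv (independent of the package's SVD path)
oracle_operator_eigs <- function(X1, X2) {
  A <- X2 %*% MASS::ginv(X1)
  ev <- eigen(A, only.values = TRUE)$values
  ev[Mod(ev) > 1e-8 * max(Mod(ev), 1)]
}

sort_eigs <- function(lambda) {
  lambda[order(-round(Mod(lambda), 10), Arg(lambda))]
}

# naive elementwise-loop RMSE
oracle_rmse <- function(pred, actual) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - actual[i])^2
  sqrt(s / length(pred))
}

# explicit mid-ranks: rank of x[i] = (#smaller) + (1 + #equal) / 2
oracle_midranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }
  r
}

# Pearson on mid-ranks via explicit sums
oracle_spearman <- function(pred, actual) {
  rx <- oracle_midranks(pred)
  ry <- oracle_midranks(actual)
  n <- length(rx)
  sx <- sum((rx - mean(rx))^2)
  sy <- sum((ry - mean(ry))^2)
  sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sx * sy)
}

# four-step hand-unrolled Holt recursion for series c(10, 12, 11, 13),
# alpha = 0.2, beta = 0.1, computed manually before the implementation:
#   l = (10, 12, 13.4, 14.872), b = (2, 2, 1.94, 1.8932)
HOLT_HAND_FORECAST <- 16.7652
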