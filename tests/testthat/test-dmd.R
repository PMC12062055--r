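test_that("snapshot pair is the one-step shift of the training matrix", {
  p <- incidence_panel("21001", 2000:2003, matrix(c(1, 2, 3, 4), 1))
  s <- build_snapshots(p)
  expect_equal(unname(s$X1), matrix(c(1, 2, 3), 1))
  expect_equal(unname(s$X2), matrix(c(2, 3, 4), 1))
  expect_equal(s$m, 4)

  big <- random_panel(6, 21, seed = 1)
  s20 <- build_snapshots(big, 2000:2019)   # 20 training snapshots
  expect_equal(ncol(s20$X1), 19)
  expect_equal(ncol(s20$X2), 19)
  expect_equal(s20$X1[, 2:19], s20$X2[, 1:18])

  expect_error(build_snapshots(big, 2000), class = "dmdcast_snapshot_error")
  expect_error(build_snapshots(big, c(2000, 2002)), "consecutive")
})

test_that("constant dynamics give eigenvalue 1 and reproduce the state", {
  p <- incidence_panel(sprintf("%05d", 1:3), 2000:2004,
                       matrix(rep(c(5, 7, 11), 5), 3))
  fit <- dmd_fit(build_snapshots(p), rank = 1)
  expect_equal(fit$eigenvalues, 1 + 0i, tolerance = 1e-10)
  expect_equal(unname(predict(fit, 1)), c(5, 7, 11), tolerance = 1e-8)
  expect_equal(unname(predict(fit, 9)), c(5, 7, 11), tolerance = 1e-8)
})

test_that("scalar geometric decay is identified exactly", {
  p <- incidence_panel("21001", 2000:2003, matrix(c(100, 90, 81, 72.9), 1))
  fit <- dmd_fit(build_snapshots(p), rank = 1)
  expect_equal(fit$eigenvalues, 0.9 + 0i, tolerance = 1e-10)
  # unit-norm mode with amplitude absorbed: phi * b = 100
  expect_equal(unname(Mod(fit$modes[1, 1] * fit$amplitudes[1])), 100,
               tolerance = 1e-8)
  expect_equal(unname(predict(fit, 5)), 65.61, tolerance = 1e-8)
})

test_that("full-rank eigenvalues match the dense pseudoinverse oracle", {
  set.seed(99)
  for (i in 1:12) {
    n <- sample(2:8, 1)
    m <- sample(4:10, 1)
    X <- matrix(rnorm(n * m, 50, 10), n, m)
    p <- incidence_panel(sprintf("%05d", 1:n), 2000 + 0:(m - 1), X)
    fit <- dmd_fit(build_snapshots(p), rank = "full")
    oracle <- oracle_operator_eigs(X[, -m, drop = FALSE], X[, -1, drop = FALSE])
    expect_equal(length(oracle), fit$rank)
    expect_lt(max(Mod(sort_eigs(fit$eigenvalues) - sort_eigs(oracle))), 1e-8)
  }
})

test_that("rank-r_true fit on a noise-free synthetic panel recovers the truth", {
  cfg <- generator_config(n_counties = 60, n_years = 12, noise_sd = 0, seed = 21)
  panel <- generate_panel(cfg)
  truth <- synthetic_truth(panel)
  fit <- dmd_fit(build_snapshots(panel), rank = 3)
  expect_lt(max(Mod(sort_eigs(fit$eigenvalues) - sort_eigs(truth$eigenvalues))), 1e-8)
  # mode subspaces agree: principal angles between the two column spans
  qf <- qr.Q(qr(fit$modes))
  qt <- qr.Q(qr(truth$modes))
  cosines <- svd(Conj(t(qf)) %*% qt)$d
  expect_lt(max(acos(pmin(cosines, 1))), 1e-6)
})

test_that("in-sample reconstruction is exact on noise-free low-rank data", {
  cfg <- generator_config(n_counties = 25, n_years = 10, noise_sd = 0, seed = 4)
  panel <- generate_panel(cfg)
  X <- panel_matrix(panel)
  fit <- dmd_fit(build_snapshots(panel), rank = "full")
  for (k in c(1, 4, 10)) {
    expect_equal(unname(predict(fit, k)), unname(X[, k]),
                 tolerance = 1e-6 * max(abs(X)))
  }
})

test_that("a contracting spectrum decays to zero at long horizons", {
  panel <- generate_panel(generator_config(n_counties = 40, n_years = 12,
                                           noise_sd = 0, seed = 6))
  fit <- dmd_fit(build_snapshots(panel), rank = 3)
  expect_true(all(Mod(fit$eigenvalues) < 1))
  # norm at step k is bounded by max|lambda|^(k-1) * sum|b| (unit-norm modes)
  bound <- max(Mod(fit$eigenvalues))^199 * sum(Mod(fit$amplitudes))
  n200 <- sqrt(sum(predict(fit, 200)^2))
  expect_lt(n200, bound + 1e-12)
  # horizon derived from the fitted spectrum at which the bound drops
  # below 1e-8 of the initial amplitude mass
  k_star <- 1 + ceiling(log(1e-8) / log(max(Mod(fit$eigenvalues))))
  expect_lt(sqrt(sum(predict(fit, k_star)^2)),
            1e-6 * sqrt(sum(predict(fit, 1)^2)))
})

test_that("rank and degeneracy errors are informative", {
  p <- random_panel(5, 6, seed = 8)
  expect_error(dmd_fit(build_snapshots(p), rank = 50),
               "numerical rank", class = "dmdcast_rank_error")
  expect_error(dmd_fit(build_snapshots(p), rank = 0), class = "dmdcast_rank_error")
  zero <- incidence_panel(sprintf("%05d", 1:3), 2000:2003, matrix(0, 3, 4))
  expect_error(dmd_fit(build_snapshots(zero)), class = "dmdcast_degenerate_error")
  expect_error(predict(dmd_fit(build_snapshots(p)), k = 0),
               class = "dmdcast_validation_error")
})

test_that("rank sweep reports Frobenius energy ratios and holdout RMSE", {
  # eigen-free check of the energy arithmetic: singular values {4, 3}
  X1 <- diag(c(4, 3)) %*% matrix(c(1, 0, 0, 1, 0, 0), 2, 3)
  p <- incidence_panel(c("00001", "00002"), 2000:2003,
                       cbind(X1, c(0.1, 0.2)))
  s <- build_snapshots(p)
  expect_equal(unname(svd(s$X1)$d), c(4, 3))
  sweep_tbl <- rank_sweep(s, holdout = c(0, 0))
  expect_equal(sweep_tbl$energy_ratio, c(16 / 25, 1), tolerance = 1e-12)

  # noise-free low-rank: error collapses and energy saturates at r_true
  panel <- generate_panel(generator_config(n_counties = 30, n_years = 10,
                                           noise_sd = 0, seed = 12))
  X <- panel_matrix(panel)
  snaps <- build_snapshots(panel, 2000:2008)
  tbl <- rank_sweep(snaps, holdout = X[, "2009"])
  expect_equal(tbl$rank, seq_len(nrow(tbl)))
  expect_lt(tbl$rmse[3], 1e-6)
  expect_gt(tbl$energy_ratio[3], 1 - 1e-10)

  # noisy: energy strictly increasing, matches the cumulative-sum oracle
  noisy <- generate_panel(generator_config(n_counties = 30, n_years = 10,
                                           noise_sd = 2, seed = 13))
  Xn <- panel_matrix(noisy)
  sn <- build_snapshots(noisy, 2000:2008)
  tn <- rank_sweep(sn, holdout = Xn[, "2009"])
  expect_true(all(diff(tn$energy_ratio) > 0))
  d2 <- svd(sn$X1)$d^2
  expect_equal(tn$energy_ratio, (cumsum(d2) / sum(d2))[tn$rank], tolerance = 1e-12)
  expect_equal(tn$energy_ratio[nrow(tn)], 1, tolerance = 1e-12)
  expect_true(all(is.finite(tn$rmse)))
})

test_that("eigen_spectrum tabulates modulus, frequency, growth and the circle flag", {
  p <- incidence_panel("21001", 2000:2003, matrix(c(100, 90, 81, 72.9), 1))
  spec <- eigen_spectrum(dmd_fit(build_snapshots(p), rank = 1))
  expect_equal(spec$modulus, 0.9, tolerance = 1e-10)
  expect_equal(spec$frequency, 0, tolerance = 1e-10)
  expect_equal(spec$growth, log(0.9), tolerance = 1e-10)
  expect_true(spec$inside_unit_circle)

  const <- incidence_panel(sprintf("%05d", 1:2), 2000:2003,
                           matrix(rep(c(5, 7), 4), 2))
  spec1 <- eigen_spectrum(dmd_fit(build_snapshots(const), rank = 1))
  expect_equal(spec1$growth, 0, tolerance = 1e-9)
  expect_false(spec1$inside_unit_circle)   # |lambda| = 1 is the boundary

  free <- generate_panel(generator_config(n_counties = 40, n_years = 12,
                                          noise_sd = 0, seed = 31))
  spec3 <- eigen_spectrum(dmd_fit(build_snapshots(free), rank = 3))
  expect_equal(mean(spec3$inside_unit_circle), 1)
})

test_that("dominant mode magnitudes separate the inflated block", {
  panel <- generate_panel(generator_config(n_counties = 120, n_years = 12,
                                           noise_sd = 0, seed = 14))
  truth <- synthetic_truth(panel)
  fit <- dmd_fit(build_snapshots(panel), rank = 3)
  dom <- dominant_mode_table(fit)
  expect_equal(dom$fips, fit$fips)
  expect_equal(Mod(attr(dom, "lambda")), 0.97, tolerance = 1e-8)
  high <- substr(dom$fips, 1, 2) == truth$high_block
  expect_gt(min(dom$magnitude[high]), max(dom$magnitude[!high]))
})

test_that("a purely oscillatory spectrum has no steady mode", {
  cfg <- generator_config(n_counties = 20, n_years = 10,
                          eigenvalues = c(0.9 * exp(0.6i), 0.9 * exp(-0.6i)),
                          noise_sd = 0, seed = 15, osc_level = 50)
  fit <- dmd_fit(build_snapshots(generate_panel(cfg)), rank = 2)
  expect_error(dominant_mode_table(fit), "angular_tol",
               class = "dmdcast_no_steady_mode_error")
})

test_that("row permutation permutes modes and leaves eigenvalues unchanged", {
  panel <- random_panel(12, 9, seed = 16)
  fit <- dmd_fit(build_snapshots(panel), rank = 4)
  set.seed(17)
  # permuting fips labels reorders the panel rows (assembly sorts by fips)
  perm_fips <- sample(sprintf("%05d", 101:112))
  X <- panel_matrix(panel)
  permuted <- incidence_panel(perm_fips, panel_years(panel), X)
  fit2 <- dmd_fit(build_snapshots(permuted), rank = 4)
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-8)
  reorder <- match(sort(perm_fips), perm_fips)
  expect_equal(unname(Mod(fit2$modes)), unname(Mod(fit$modes[reorder, ])),
               tolerance = 1e-8)
})

test_that("predictions are real for conjugate-closed spectra", {
  panel <- generate_panel(generator_config(n_counties = 30, n_years = 12,
                                           noise_sd = 2, seed = 18))
  fit <- dmd_fit(build_snapshots(panel), rank = 3)   # pair + real mode retained
  raw <- fit$modes %*% (fit$eigenvalues^10 * fit$amplitudes)
  expect_lt(max(abs(Im(raw))), 1e-8 * sqrt(sum(Mod(raw)^2)))
})

test_that("orthonormality and eigen-relation invariants hold after fitting", {
  panel <- random_panel(10, 9, seed = 19)
  fit <- dmd_fit(build_snapshots(panel), rank = 5)
  expect_equal(crossprod(fit$U), diag(5), tolerance = 1e-10)
  expect_equal(crossprod(fit$V), diag(5), tolerance = 1e-10)
  expect_false(is.unsorted(rev(fit$S)))
  resid <- fit$A_tilde %*% fit$W - fit$W %*% diag(fit$eigenvalues)
  expect_lt(max(Mod(resid)), 1e-8 * max(Mod(fit$W)) * max(abs(fit$A_tilde)))
})

test_that("model JSON bundle round-trips and predicts identically", {
  panel <- generate_panel(generator_config(n_counties = 15, n_years = 8,
                                           noise_sd = 1, seed = 20))
  fit <- dmd_fit(build_snapshots(panel), rank = 3)
  path <- tempfile(fileext = ".json")
  write_dmd_json(fit, path)
  back <- read_dmd_json(path)
  expect_equal(back$eigenvalues, fit$eigenvalues, tolerance = 1e-12)
  expect_equal(predict(back, 9), predict(fit, 9), tolerance = 1e-12)
})
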