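test_that("lag design aligns counties with a consecutive feature window", {
  panel <- random_panel(2, 4, seed = 1)
  des <- make_lag_design(panel, 2000:2002, 2003)
  expect_equal(dim(des$features), c(2, 3))
  expect_equal(length(des$target), 2)
  expect_equal(des$lag, 3)
  expect_equal(des$fips, panel$fips)
  expect_error(make_lag_design(panel, 2000:2001, 2003),
               class = "dmdcast_alignment_error")
  # prediction-only design: target year beyond the panel
  shifted <- make_lag_design(panel, 2001:2003, 2004)
  expect_null(shifted$target)
})

test_that("Holt recursion hits fixed points, linear trends, and the hand oracle", {
  expect_equal(holt_forecast(rep(7.5, 10), alpha = 0.3, beta = 0.6), 7.5)
  # exact linear series: l_t tracks y_t, b_t tracks the slope, for any weights
  y <- 3 + 1.7 * (1:9)
  expect_equal(holt_forecast(y, alpha = 0.42, beta = 0.9), 3 + 1.7 * 10)
  expect_equal(holt_forecast(c(10, 12, 11, 13), alpha = 0.2, beta = 0.1),
               HOLT_HAND_FORECAST, tolerance = 1e-12)
  expect_error(holt_forecast(5), class = "dmdcast_validation_error")
  expect_error(holt_forecast(c(1, 2), alpha = 0), class = "dmdcast_validation_error")
})

test_that("OLS recovers exact linear relations and matches normal equations", {
  panel <- random_panel(50, 6, seed = 2)
  X <- panel_matrix(panel)
  # target exactly doubles the last feature column
  doubled <- incidence_panel(panel$fips, 2000:2005,
                             cbind(X[, 1:5], 2 * X[, 5]))
  fit <- linreg_fit(make_lag_design(doubled, 2000:2004, 2005))
  expect_equal(as.numeric(unclass(fit)), c(0, 0, 0, 0, 0, 2), tolerance = 1e-8)

  des <- make_lag_design(panel, 2000:2004, 2005)
  fit2 <- linreg_fit(des)
  Xd <- cbind(1, des$features)
  beta_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% des$target)  # (X'X)^-1 X'y
  expect_equal(as.numeric(unclass(fit2)), as.numeric(beta_oracle),
               tolerance = 1e-8)

  one_row <- make_lag_design(random_panel(1, 6, seed = 3), 2000:2004, 2005)
  fit3 <- linreg_fit(one_row)
  expect_true(attr(fit3, "rank_deficient"))
  expect_equal(unname(predict(fit3, one_row$features)), one_row$target,
               tolerance = 1e-8)
})

test_that("OLS forecasts are equivariant under rate rescaling", {
  panel <- random_panel(40, 7, seed = 4)
  X <- panel_matrix(panel)
  des <- make_lag_design(panel, 2000:2004, 2005)
  newf <- X[, 2:6]
  base <- predict(linreg_fit(des), newf)
  scaled_panel <- incidence_panel(panel$fips, panel_years(panel), 100 * X)
  des100 <- make_lag_design(scaled_panel, 2000:2004, 2005)
  expect_equal(predict(linreg_fit(des100), 100 * newf), 100 * base,
               tolerance = 1e-6)
})

test_that("grid search enumerates every cell and reports its own minimum", {
  panel <- random_panel(60, 6, seed = 5)
  des <- make_lag_design(panel, 2000:2004, 2005)
  fit <- fit_ml_regressor(des, "svm_rbf", seed = 1)   # default paper grid
  expect_equal(nrow(fit$grid_table), 16)              # 4 cost x 4 gamma
  expect_equal(fit$best$train_rmse, min(fit$grid_table$train_rmse))

  small <- fit_ml_regressor(des, "random_forest",
                            grid = list(num_trees = c(50, 100), max_depth = c(2, 4)),
                            seed = 1)
  expect_equal(nrow(small$grid_table), 4)
})

test_that("duplicated grid cells tie and the first in order wins", {
  panel <- random_panel(40, 6, seed = 6)
  des <- make_lag_design(panel, 2000:2004, 2005)
  fit <- fit_ml_regressor(des, "svm_rbf",
                          grid = data.frame(cost = c(2, 2), gamma = c(0.5, 0.5)),
                          seed = 1)
  expect_equal(fit$grid_table$train_rmse[1], fit$grid_table$train_rmse[2])
  expect_identical(fit$best, fit$grid_table[1, ])
})

test_that("ML fits are reproducible and accurate on a linear truth", {
  set.seed(7)
  n <- 200
  X <- matrix(runif(n * 5, 30, 90), n, 5,
              dimnames = list(NULL, 2000:2004))
  y <- drop(X %*% c(0.1, 0.1, 0.2, 0.2, 0.4))
  panel <- incidence_panel(sprintf("%05d", 1:n), 2000:2005, cbind(X, y))
  des <- make_lag_design(panel, 2000:2004, 2005)
  grid_rf <- list(num_trees = 100, max_depth = c(5, 10))
  a <- fit_ml_regressor(des, "random_forest", grid = grid_rf, seed = 11)
  b <- fit_ml_regressor(des, "random_forest", grid = grid_rf, seed = 11)
  expect_identical(predict(a, des$features), predict(b, des$features))
  expect_lt(a$best$train_rmse, sd(y))   # far below the no-skill floor
  s <- fit_ml_regressor(des, "svm_rbf", grid = list(cost = c(1, 10), gamma = 0.1),
                        seed = 11)
  expect_lt(s$best$train_rmse, sd(y))
  expect_error(fit_ml_regressor(des, "svm_rbf", grid = list()),
               class = "dmdcast_config_error")
})

test_that("forecast_all nails exact-linear truth and keeps a stable shape", {
  panel <- ramp_panel(n = 25, m = 10, seed = 8)
  X <- panel_matrix(panel)
  fc <- forecast_all(panel, models = c("dmd", "holt", "linreg"))
  expect_s3_class(fc, "forecast_result")
  expect_equal(attr(fc, "target_year"), 2009)
  actual <- unname(X[, "2009"])
  expect_equal(fc$actual, actual)
  expect_lt(max(abs(fc$dmd - actual)), 1e-6)
  expect_lt(max(abs(fc$holt - actual)), 1e-6)
  expect_lt(max(abs(fc$linreg - actual)), 1e-6)
})

test_that("forecast_all runs all six models, finite and seed-reproducible", {
  panel <- generate_panel(generator_config(n_counties = 80, n_years = 12,
                                           noise_sd = 2, seed = 9))
  grids <- list(rf = list(num_trees = 100, max_depth = 3),
                gbm = list(num_trees = 100, interaction_depth = 2),
                svm = list(cost = c(1, 10), gamma = 0.1))
  fc1 <- forecast_all(panel, grids = grids, seed = 23)
  expect_named(fc1, c("fips", "actual", "dmd", "holt", "linreg", "rf", "gbm", "svm"))
  expect_equal(nrow(fc1), 80)
  expect_true(all(is.finite(as.matrix(fc1[, -1]))))
  fc2 <- forecast_all(panel, grids = grids, seed = 23)
  expect_identical(fc1, fc2)
})

test_that("a failing model is dropped with a warning, others survive", {
  panel <- random_panel(5, 6, seed = 10)
  # rank above numerical rank makes the DMD leg fail
  expect_warning(
    fc <- forecast_all(panel, models = c("dmd", "holt"), rank = 50),
    "dmd"
  )
  expect_false("dmd" %in% names(fc))
  expect_true("holt" %in% names(fc))
  expect_match(attr(fc, "failures")[["dmd"]], "rank")
})
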