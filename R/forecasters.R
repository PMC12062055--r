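#' Lagged supervised design for cross-county regression forecasters
#'
#' Frames one-step forecasting as supervised regression with counties as
#' rows: each county's rates over `feature_years` (a window of L consecutive
#' years) are the features, its rate in the following year the target. The
#' same design, shifted forward one year, produces out-of-window forecasts.
#'
#' @param panel a complete [incidence_panel()].
#' @param feature_years consecutive years used as features.
#' @param target_year the year to predict; must be `max(feature_years) + 1`.
#' @return a list of class `lag_design`: `features` (n x L matrix, columns
#'   named by year), `target` (length-n vector, or `NULL` if `target_year`
#'   is absent from the panel, for prediction-only designs), `fips`, `lag`,
#'   `feature_years`, `target_year`.
#' @export
make_lag_design <- function(panel, feature_years, target_year) {
  panel <- as_incidence_panel(panel)
  yrs <- panel_years(panel)
  feature_years <- as.integer(feature_years)
  target_year <- as.integer(target_year)
  if (!all(feature_years %in% yrs)) {
    abort_validation("feature_years must all be panel years")
  }
  if (length(feature_years) > 1L && any(diff(feature_years) != 1L)) {
    abort_validation("feature_years must be consecutive")
  }
  if (target_year != max(feature_years) + 1L) {
    abort_validation(sprintf(
      "target_year (%d) must immediately follow the last feature year (%d)",
      target_year, max(feature_years)
    ), class = "dmdcast_alignment_error")
  }
  X <- panel_matrix(panel)[, as.character(feature_years), drop = FALSE]
  y <- if (target_year %in% yrs) panel_matrix(panel)[, as.character(target_year)] else NULL
  structure(list(features = X, target = unname(y), fips = panel$fips,
                 lag = length(feature_years), feature_years = feature_years,
                 target_year = target_year),
            class = "lag_design")
}

#' Holt exponential smoothing with trend: one-step forecast
#'
#' Maintains a level and a trend by the recursions
#' \eqn{l_t = \alpha y_t + (1-\alpha)(l_{t-1}+b_{t-1})},
#' \eqn{b_t = \beta(l_t-l_{t-1}) + (1-\beta)b_{t-1}}, initialized with
#' \eqn{l_1 = y_1}, \eqn{b_1 = y_2 - y_1} and iterated over `t = 2..m`; the
#' one-step forecast is \eqn{l_m + b_m}. On an exactly linear series the
#' recursion is exact for any smoothing weights.
#'
#' @param y numeric series, length >= 2.
#' @param alpha level smoothing weight in (0,1); default 0.2.
#' @param beta trend smoothing weight in (0,1); default 0.1.
#' @return the one-step-ahead forecast (scalar).
#' @examples
#' holt_forecast(c(10, 12, 11, 13), alpha = 0.2, beta = 0.1)
#' @export
holt_forecast <- function(y, alpha = 0.2, beta = 0.1) {
  if (length(y) < 2L) {
    abort_validation("Holt smoothing needs at least 2 observations")
  }
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    abort_validation("alpha and beta must lie strictly in (0, 1)")
  }
  l <- y[1]
  b <- y[2] - y[1]
  for (t in 2:length(y)) {
    l_prev <- l
    l <- alpha * y[t] + (1 - alpha) * (l_prev + b)
    b <- beta * (l - l_prev) + (1 - beta) * b
  }
  l + b
}

#' Ordinary least squares on a lag design
#'
#' Fits intercept + one weight per lagged year. With a rank-deficient design
#' the minimum-norm solution is returned and the fit is flagged
#' (`attr(., "rank_deficient")`).
#'
#' @param design a [make_lag_design()] with a non-`NULL` target.
#' @return coefficient vector of class `linreg_forecaster`, length
#'   `lag + 1`, names `(Intercept)` then the feature years.
#' @export
linreg_fit <- function(design) {
  stopifnot(inherits(design, "lag_design"))
  if (is.null(design$target)) {
    abort_validation("design has no target column to fit against")
  }
  X <- cbind(`(Intercept)` = 1, design$features)
  qr_x <- qr(X)
  deficient <- qr_x$rank < ncol(X)
  if (!deficient) {
    coefs <- qr.coef(qr_x, design$target)
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
    keep <- sv$d > tol
    coefs <- drop(sv$v[, keep, drop = FALSE] %*%
                    (crossprod(sv$u[, keep, drop = FALSE], design$target) / sv$d[keep]))
    names(coefs) <- colnames(X)
  }
  structure(coefs, class = "linreg_forecaster", rank_deficient = deficient)
}

#' @export
predict.linreg_forecaster <- function(object, newfeatures, ...) {
  drop(cbind(1, as.matrix(newfeatures)) %*% unclass(object))
}

default_grid <- function(family) {
  switch(family,
    random_forest = expand.grid(num_trees = c(100, 300, 500),
                                max_depth = c(3, 5, 10)),
    gradient_boosting = expand.grid(num_trees = c(100, 300, 500),
                                    interaction_depth = c(1, 3, 5)),
    svm_rbf = expand.grid(cost = c(0.1, 1, 10, 100),
                          gamma = c(0.1, 1, 10, 100)),
    abort_validation(sprintf("unknown regressor family '%s'", family),
                     class = "dmdcast_config_error")
  )
}

fit_one_cell <- function(family, X, y, cell, seed, scaling = NULL) {
  if (family == "random_forest") {
    df <- data.frame(.y = y, X, check.names = FALSE)
    ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = cell$num_trees, max.depth = cell$max_depth,
      seed = seed, num.threads = 1
    )
  } else if (family == "gradient_boosting") {
    with_seed(seed, xgboost::xgboost(
      x = X, y = y, nrounds = cell$num_trees,
      max_depth = cell$interaction_depth, learning_rate = 0.1,
      objective = "reg:squarederror", nthreads = 1, verbosity = 0
    ))
  } else {
    Xs <- scale_features(X, scaling)
    e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
               cost = cell$cost, gamma = cell$gamma, scale = FALSE)
  }
}

predict_one <- function(family, model, X, scaling = NULL) {
  if (family == "random_forest") {
    predict(model, data = data.frame(X, check.names = FALSE))$predictions
  } else if (family == "gradient_boosting") {
    predict(model, X)
  } else {
    unname(predict(model, scale_features(X, scaling)))
  }
}

scale_features <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$center), 2, scaling$scale, `/`)
}

#' Grid-searched machine-learning regressors on a lag design
#'
#' Fits random forest, gradient-boosted trees, or RBF-kernel support vector
#' regression over an exhaustively enumerated hyperparameter grid, scoring
#' every cell by RMSE on the training data, selecting the lowest-RMSE cell
#' (ties broken by enumeration order) and refitting it on the full design.
#' SVM features are standardized (zero mean, unit variance per lag column)
#' with the training statistics, so absolute `gamma` values have a fixed
#' scale meaning. Deterministic given `seed`.
#'
#' Default grids: random forest `num_trees` \{100, 300, 500\} x `max_depth`
#' \{3, 5, 10\}; gradient boosting `num_trees` \{100, 300, 500\} x
#' `interaction_depth` \{1, 3, 5\}; SVM `cost` \{0.1, 1, 10, 100\} x
#' `gamma` \{0.1, 1, 10, 100\} (16 cells).
#'
#' @param design a [make_lag_design()] with target.
#' @param family one of `"random_forest"`, `"gradient_boosting"`,
#'   `"svm_rbf"`.
#' @param grid a data frame of candidate cells, or a named list of candidate
#'   vectors expanded with `expand.grid()` (first column varies fastest).
#'   Default: the family's grid above.
#' @param seed integer seed controlling every stochastic fit.
#' @return an object of class `ml_forecaster`: the refit `model`, `best`
#'   (one-row tibble of chosen hyperparameters + training RMSE),
#'   `grid_table` (all cells with their training RMSE), `family`, `seed`.
#' @export
fit_ml_regressor <- function(design, family = c("random_forest", "gradient_boosting", "svm_rbf"),
                             grid = NULL, seed = 1L) {
  stopifnot(inherits(design, "lag_design"))
  if (is.null(design$target)) {
    abort_validation("design has no target column to fit against")
  }
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  if (nrow(grid) == 0L) {
    abort_validation("hyperparameter grid is empty", class = "dmdcast_config_error")
  }
  X <- design$features
  y <- design$target
  scaling <- if (family == "svm_rbf") {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    list(center = ctr, scale = scl)
  } else NULL

  rmse_by_cell <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- fit_one_cell(family, X, y, grid[i, , drop = FALSE], seed, scaling)
    rmse(predict_one(family, fit, X, scaling), y)
  }, numeric(1))

  best_i <- which.min(rmse_by_cell)   # first minimum = enumeration-order tie-break
  final <- fit_one_cell(family, X, y, grid[best_i, , drop = FALSE], seed, scaling)
  grid_table <- tibble::as_tibble(grid)
  grid_table$train_rmse <- rmse_by_cell

  structure(list(
    family = family, model = final,
    best = grid_table[best_i, , drop = FALSE],
    grid_table = grid_table, scaling = scaling, seed = seed,
    feature_years = design$feature_years
  ), class = "ml_forecaster")
}

#' @export
predict.ml_forecaster <- function(object, newfeatures, ...) {
  predict_one(object$family, object$model, as.matrix(newfeatures), object$scaling)
}

#' @export
print.ml_forecaster <- function(x, ...) {
  cat(sprintf("<ml_forecaster> %s, %d grid cells searched\n",
              x$family, nrow(x$grid_table)))
  print(x$best)
  invisible(x)
}

#' Forecast the target year with every configured model
#'
#' Runs the full comparison protocol on one panel: DMD (fit on the training
#' window, one step ahead), Holt smoothing county-by-county, and the lagged
#' regression forecasters (OLS, random forest, gradient boosting, SVM)
#' trained on `years[1..T-1] -> year T` and applied to the window shifted
#' one year forward to predict `target_year = T + 1`. A model that fails is
#' logged and dropped; the others proceed.
#'
#' @param panel a complete [incidence_panel()].
#' @param models character subset of
#'   `c("dmd", "holt", "linreg", "rf", "gbm", "svm")`.
#' @param train_end last training year (default: the panel's second-to-last
#'   year, leaving the final year as the scoring holdout).
#' @param rank DMD truncation rank (default `"full"`).
#' @param alpha,beta Holt smoothing weights.
#' @param grids named list (`rf`, `gbm`, `svm`) overriding the default
#'   hyperparameter grids of [fit_ml_regressor()].
#' @param seed integer seed shared by the stochastic fits.
#' @return a tibble of class `forecast_result`: `fips`, `actual` (when the
#'   target year is present in the panel), then one prediction column per
#'   successful model. Attributes: `target_year`, `train_years`, `failures`
#'   (named character vector of error messages).
#' @export
forecast_all <- function(panel,
                         models = c("dmd", "holt", "linreg", "rf", "gbm", "svm"),
                         train_end = NULL, rank = "full",
                         alpha = 0.2, beta = 0.1, grids = list(), seed = 1L) {
  panel <- as_incidence_panel(panel)
  yrs <- panel_years(panel)
  train_end <- as.integer(train_end %||% (max(yrs) - 1L))
  target_year <- train_end + 1L
  if (!train_end %in% yrs || train_end <= min(yrs)) {
    abort_validation("train_end must be a panel year with at least one year before it")
  }
  models <- match.arg(models, several.ok = TRUE)
  train_years <- yrs[yrs <= train_end]
  X <- panel_matrix(panel)
  if (anyNA(X)) {
    abort_validation("panel has missing cells; run filter_complete() first")
  }

  family_of <- c(rf = "random_forest", gbm = "gradient_boosting", svm = "svm_rbf")
  fit_design <- make_lag_design(panel, head(train_years, -1), train_end)
  pred_features <- X[, as.character(train_years[-1]), drop = FALSE]
  colnames(pred_features) <- colnames(fit_design$features)  # same lag offsets

  preds <- list()
  failures <- character()
  for (mod in models) {
    res <- tryCatch({
      switch(mod,
        dmd = {
          fit <- dmd_fit(build_snapshots(panel, train_years), rank = rank)
          unname(predict(fit, k = fit$m + 1L))
        },
        holt = apply(X[, as.character(train_years), drop = FALSE], 1,
                     holt_forecast, alpha = alpha, beta = beta),
        linreg = unname(predict(linreg_fit(fit_design), pred_features)),
        {
          fit <- fit_ml_regressor(fit_design, family_of[[mod]],
                                  grid = grids[[mod]], seed = seed)
          unname(predict(fit, pred_features))
        }
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[mod] <- conditionMessage(res)
      warn(sprintf("model '%s' failed and was dropped: %s", mod, failures[mod]))
    } else {
      preds[[mod]] <- as.numeric(res)
    }
  }
  if (length(preds) == 0L) {
    abort_runtime("every configured model failed", class = "dmdcast_all_models_failed")
  }

  out <- tibble::tibble(fips = panel$fips)
  if (target_year %in% yrs) out$actual <- unname(X[, as.character(target_year)])
  for (mod in names(preds)) out[[mod]] <- preds[[mod]]
  structure(out, class = c("forecast_result", class(out)),
            target_year = target_year, train_years = train_years,
            failures = failures)
}
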