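# End-to-end pipeline runners behind the command-line interface. Each takes
# a run configuration (a named list or a YAML/JSON file path), writes its
# artifacts under `out_dir`, and returns the artifact paths invisibly.
# Validation problems raise `dmdcast_validation_error`, model/computation
# problems `dmdcast_runtime_error`; the CLI wrapper maps these to exit
# codes 1 and 2.

#' Load and validate a run configuration
#'
#' A configuration is a named list with optional blocks: `synthetic`
#' (arguments for [generator_config()]), `input` (`path` and `format`
#' `"wide"` or `"long"` plus column mappings), `train_end`, `rank`
#' (`"full"` or integer), `models`, `holt` (`alpha`, `beta`), `grids`
#' (`rf`/`gbm`/`svm` candidate lists), `seed`, `out_dir`.
#'
#' @param config a named list, or path to a YAML or JSON file.
#' @return the validated configuration list, class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort_validation(sprintf("config file not found: %s", config))
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort_validation("config must be a list or a file path")
  config$seed <- as.integer(config$seed %||% 1L)
  config$rank <- config$rank %||% "full"
  config$out_dir <- config$out_dir %||% "."
  if (!is.null(config$input) && is.null(config$input$path)) {
    abort_validation("config$input must name a 'path'")
  }
  if (!is.null(config$input$path) && !file.exists(config$input$path)) {
    abort_validation(sprintf("input file not found: %s", config$input$path))
  }
  structure(config, class = c("run_config", "list"))
}

resolve_config <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg
}

config_generator <- function(cfg) {
  args <- cfg$synthetic %||% list()
  if (!is.null(args$eigenvalues) && !is.complex(args$eigenvalues)) {
    # YAML has no complex type: accept a list of [re, im] pairs or reals
    ev <- args$eigenvalues
    if (is.list(ev)) {
      args$eigenvalues <- vapply(ev, function(z) {
        z <- as.numeric(unlist(z))
        complex(real = z[1], imaginary = if (length(z) > 1) z[2] else 0)
      }, complex(1))
    }
  }
  if (is.null(args$seed)) args$seed <- cfg$seed
  do.call(generator_config, args)
}

load_panel <- function(cfg) {
  if (!is.null(cfg$input)) {
    fmt <- cfg$input$format %||% "wide"
    if (fmt == "wide") {
      read_panel_csv(cfg$input$path)
    } else {
      records <- read_incidence_csv(cfg$input$path,
                                    fips = cfg$input$fips %||% "fips",
                                    year = cfg$input$year %||% "year",
                                    rate = cfg$input$rate %||% "rate")
      assemble_panel(records)
    }
  } else if (!is.null(cfg$synthetic)) {
    generate_panel(config_generator(cfg))
  } else {
    abort_validation("config needs either an 'input' or a 'synthetic' block")
  }
}

write_summary <- function(cfg, path, extra = list()) {
  payload <- c(list(seed = cfg$seed, out_dir = cfg$out_dir,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
               extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a synthetic panel and write it to disk
#'
#' Writes `panel.csv` (wide, complete counties only when missingness was
#' injected the raw panel keeps its `NA` cells as empty fields in a long
#' sidecar), `truth.json` (the generating system), and `run_summary.json`.
#'
#' @param config a run configuration (list or file path) with a `synthetic`
#'   block.
#' @param seed optional override of `config$seed`.
#' @param out_dir optional override of `config$out_dir`.
#' @return named character vector of artifact paths, invisibly.
#' @export
run_simulate <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- resolve_config(config, seed, out_dir)
  if (is.null(cfg$synthetic)) cfg$synthetic <- list()
  gen <- config_generator(cfg)
  panel <- generate_panel(gen)
  truth <- synthetic_truth(panel)

  paths <- c(panel = file.path(cfg$out_dir, "panel.csv"),
             truth = file.path(cfg$out_dir, "truth.json"),
             summary = file.path(cfg$out_dir, "run_summary.json"))
  if (anyNA(panel_matrix(panel))) {
    # panels with injected missingness round-trip through the long dialect,
    # which represents missing cells as empty fields
    records <- tidy.incidence_panel(panel)
    readr::write_csv(records, paths[["panel"]], na = "", progress = FALSE)
  } else {
    write_panel_csv(panel, paths[["panel"]])
  }
  write_truth_json(truth, paths[["truth"]])
  message(sprintf("simulated %d counties x %d years (r_true=%d, noise_sd=%g, seed=%d)",
                  nrow(panel), length(panel_years(panel)), gen$r_true,
                  gen$noise_sd, gen$seed))
  write_summary(cfg, paths[["summary"]], list(
    command = "simulate", n_counties = nrow(panel),
    n_years = length(panel_years(panel)), r_true = gen$r_true,
    noise_sd = gen$noise_sd, missing = missing_log(panel)
  ))
  invisible(paths)
}

#' Fit DMD on a panel and write the spectral diagnostics
#'
#' Filters incomplete counties (logging them by FIPS), fits DMD on the
#' training window, and writes four artifacts: `dmd_model.json`,
#' `spectrum.csv`, `rank_sweep.csv` (holdout = the year after the training
#' window, which must be present in the panel), and `dominant_modes.csv`
#' (keyed by fips for choropleth joins).
#'
#' @inheritParams run_simulate
#' @export
run_fit_dmd <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- resolve_config(config, seed, out_dir)
  panel <- load_panel(cfg)
  panel <- filter_complete(panel)
  dropped <- dropped_counties(panel)
  if (length(dropped)) {
    message(sprintf("dropped %d counties with missing years: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  yrs <- panel_years(panel)
  train_end <- as.integer(cfg$train_end %||% (max(yrs) - 1L))
  train_years <- yrs[yrs <= train_end]
  snaps <- build_snapshots(panel, train_years)
  rank <- if (identical(cfg$rank, "full")) "full" else as.integer(cfg$rank)
  model <- dmd_fit(snaps, rank = rank)

  holdout_year <- train_end + 1L
  if (!holdout_year %in% yrs) {
    abort_validation(sprintf(
      "holdout year %d absent from panel; rank sweep needs it", holdout_year))
  }
  holdout <- panel_matrix(panel)[, as.character(holdout_year)]
  sweep_tbl <- rank_sweep(snaps, holdout)

  paths <- c(model = file.path(cfg$out_dir, "dmd_model.json"),
             spectrum = file.path(cfg$out_dir, "spectrum.csv"),
             rank_sweep = file.path(cfg$out_dir, "rank_sweep.csv"),
             dominant = file.path(cfg$out_dir, "dominant_modes.csv"),
             summary = file.path(cfg$out_dir, "run_summary.json"))
  write_dmd_json(model, paths[["model"]])
  readr::write_csv(eigen_spectrum(model), paths[["spectrum"]], progress = FALSE)
  readr::write_csv(tibble::as_tibble(sweep_tbl), paths[["rank_sweep"]], progress = FALSE)
  dom <- tryCatch(dominant_mode_table(model), dmdcast_no_steady_mode_error = function(e) NULL)
  if (!is.null(dom)) {
    readr::write_csv(dom, paths[["dominant"]], progress = FALSE)
  } else {
    message("no steady (zero-frequency) mode retained; dominant_modes.csv skipped")
    paths <- paths[names(paths) != "dominant"]
  }
  write_summary(cfg, paths[["summary"]], list(
    command = "fit-dmd", rank = model$rank,
    numerical_rank = model$numerical_rank,
    n_counties = model$n, train_years = range(train_years),
    dropped = as.list(dropped)
  ))
  invisible(paths)
}

#' Run the full six-model comparison and write the evaluation report
#'
#' Forecasts the year after `train_end` with every configured model and
#' scores RMSE and Spearman correlation against the panel's actual rates
#' for that year. Writes `forecasts.csv`, `report.csv`, `report.json`, and
#' `run_summary.json`.
#'
#' @inheritParams run_simulate
#' @export
run_compare <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- resolve_config(config, seed, out_dir)
  panel <- load_panel(cfg)
  panel <- filter_complete(panel)
  dropped <- dropped_counties(panel)
  if (length(dropped)) {
    message(sprintf("dropped %d incomplete counties", length(dropped)))
  }
  yrs <- panel_years(panel)
  train_end <- as.integer(cfg$train_end %||% (max(yrs) - 1L))
  if (!(train_end + 1L) %in% yrs) {
    abort_validation(sprintf(
      "target year %d absent from panel; cannot score forecasts", train_end + 1L))
  }
  models <- cfg$models %||% c("dmd", "holt", "linreg", "rf", "gbm", "svm")
  grids <- lapply(cfg$grids %||% list(), function(g) lapply(g, unlist))
  fc <- forecast_all(panel, models = models, train_end = train_end,
                     rank = if (identical(cfg$rank, "full")) "full" else as.integer(cfg$rank),
                     alpha = cfg$holt$alpha %||% 0.2,
                     beta = cfg$holt$beta %||% 0.1,
                     grids = grids, seed = cfg$seed)
  report <- evaluate_models(fc)

  paths <- c(forecasts = file.path(cfg$out_dir, "forecasts.csv"),
             report_csv = file.path(cfg$out_dir, "report.csv"),
             report_json = file.path(cfg$out_dir, "report.json"),
             summary = file.path(cfg$out_dir, "run_summary.json"))
  readr::write_csv(tibble::as_tibble(fc), paths[["forecasts"]], progress = FALSE)
  readr::write_csv(tibble::as_tibble(report), paths[["report_csv"]], progress = FALSE)
  jsonlite::write_json(tibble::as_tibble(report), paths[["report_json"]],
                       dataframe = "rows", digits = NA)
  write_summary(cfg, paths[["summary"]], list(
    command = "compare", target_year = attr(fc, "target_year"),
    models = names(fc)[!names(fc) %in% c("fips", "actual")],
    failures = as.list(attr(fc, "failures")), dropped = as.list(dropped)
  ))
  invisible(paths)
}
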