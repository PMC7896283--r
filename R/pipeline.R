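# End-to-end pipeline: simulate -> metrics -> climate -> trends ->
# driver selection -> attribution, with seed fan-out, stage outputs as plain
# CSV/YAML, and a checksum manifest.

VALID_METRICS <- c(
  "max_daily", "mean_daily", "median_daily", "start_doy", "end_doy",
  "season_length", "spring_integral", "summer_integral", "fall_integral",
  "annual_integral"
)

CLIMATE_PREDICTORS <- c(
  "mat", "map", "spring_t", "spring_p", "spring_frost",
  "summer_t", "summer_p", "summer_frost", "co2"
)

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default: season-threshold
#' percentile 30, delta-AIC window 3, anomaly baseline 1850--1880, 50-year
#' moving-average window, attribution periods 1990--2018 and 2003--2018, and
#' the four headline metrics (annual and spring integrals, season start date,
#' season length). Configurations round-trip losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n_stations,years,n_models,acc_fraction,seed Synthetic-study
#'   dimensions and planted anthropogenic fraction (see [truth_params()]).
#' @param sampling_mode Record subsampling mode (see
#'   [simulate_pollen_study()]).
#' @param percentile Season-threshold percentile.
#' @param pooled Pool threshold measurements across years (see
#'   [station_thresholds()]).
#' @param aic_window Delta-AIC window for the plausible model set.
#' @param baseline Anomaly climatology years.
#' @param ma_window Moving-average window (years) for the ACC signal.
#' @param periods List of attribution windows.
#' @param metrics Metrics carried through trend detection and attribution.
#' @param selection List: `enabled` (fit the all-subsets table), `response`,
#'   `predictors`.
#' @param truth Named list of extra overrides passed to [truth_params()]
#'   (e.g. `beta_t`, `phenology_shift`).
#' @return Object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(n_stations = 60,
                            years = 1990:2018,
                            n_models = 22,
                            acc_fraction = 0.75,
                            sampling_mode = "seasonal",
                            percentile = 30,
                            pooled = TRUE,
                            aic_window = 3,
                            baseline = c(1850, 1880),
                            ma_window = 50,
                            periods = list(c(1990, 2018), c(2003, 2018)),
                            metrics = c(
                              "annual_integral", "spring_integral",
                              "start_doy", "season_length"
                            ),
                            selection = list(
                              enabled = FALSE,
                              response = "annual_integral",
                              predictors = CLIMATE_PREDICTORS
                            ),
                            truth = list(),
                            seed = 1L) {
  config <- list(
    n_stations = as.integer(n_stations),
    years = as.integer(years),
    n_models = as.integer(n_models),
    acc_fraction = acc_fraction,
    sampling_mode = sampling_mode,
    percentile = percentile,
    pooled = isTRUE(pooled),
    aic_window = aic_window,
    baseline = as.integer(baseline),
    ma_window = as.integer(ma_window),
    periods = lapply(periods, as.integer),
    metrics = metrics,
    selection = utils::modifyList(
      list(
        enabled = FALSE, response = "annual_integral",
        predictors = CLIMATE_PREDICTORS
      ),
      selection
    ),
    truth = truth,
    seed = as.integer(seed)
  )
  validate_pipeline_config(config)
  structure(config, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  bad <- setdiff(config$metrics, VALID_METRICS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown metric name(s): %s.", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(config$selection$predictors, CLIMATE_PREDICTORS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown predictor(s): %s.", paste(bad, collapse = ", ")))
  }
  if (config$percentile < 0 || config$percentile > 100) {
    abort("`percentile` must lie in [0, 100].")
  }
  if (length(config$baseline) != 2 || diff(config$baseline) <= 0) {
    abort("`baseline` must be two increasing years.")
  }
  for (p in config$periods) {
    if (length(p) != 2 || p[1] >= p[2]) {
      abort("Each period must be c(start_year, end_year) with start < end.")
    }
    if (p[1] < min(config$years) || p[2] > max(config$years)) {
      abort(sprintf(
        "Period %d-%d lies outside the study years %d-%d.",
        p[1], p[2], min(config$years), max(config$years)
      ))
    }
  }
  invisible(config)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML serialization.
#' @export
write_pipeline_config <- function(config, path) {
  validate_pipeline_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full detection-and-attribution pipeline
#'
#' Executes the stages in order — simulate, pollen metrics, climate
#' processing (covariates, ACC signal, counterfactuals), trend detection,
#' optional all-subsets driver selection, ensemble attribution — writing
#' every stage output as plain CSV/YAML under `out_dir` together with a
#' `manifest.json` (configuration, seed, file checksums, versions). A stage
#' failure halts the run naming the failing stage; earlier outputs are
#' retained. The global seed fans out to independent per-stage seeds, so
#' results are reproducible end to end.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`bundle`,
#'   `metrics`, `climate`, `acc`, `trends`, `selection`, `attribution`,
#'   `attribution_summary`) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # -- stage 1: synthetic study ------------------------------------------
  bundle <- run_stage("simulate", {
    truth_args <- utils::modifyList(
      list(
        n_stations = config$n_stations, years = config$years,
        acc_fraction = config$acc_fraction,
        seed = stage_seed(config$seed, 1L)
      ),
      config$truth
    )
    truth <- do.call(truth_params, truth_args)
    b <- simulate_pollen_study(truth,
      n_models = config$n_models,
      sampling_mode = config$sampling_mode
    )
    write_stage_csv(b$records, out_dir, "records.csv")
    write_stage_csv(b$stations, out_dir, "stations.csv")
    write_stage_csv(b$co2, out_dir, "co2.csv")
    truth_scalars <- b$truth[setdiff(names(b$truth), "stations")]
    yaml::write_yaml(truth_scalars, file.path(out_dir, "truth.yaml"))
    b
  })

  # -- stage 2: pollen metrics -------------------------------------------
  metrics <- run_stage("metrics", {
    m <- pollen_metrics(bundle$records,
      percentile = config$percentile,
      pooled = config$pooled
    )
    write_stage_csv(m, out_dir, "metrics.csv")
    write_stage_csv(attr(m, "exclusions"), out_dir, "exclusions.csv")
    m
  })

  # -- stage 3: climate covariates and counterfactuals -------------------
  stage3 <- run_stage("climate", {
    monthly <- extract_station_series(bundle$observed_climate, bundle$stations)
    covars <- annual_covariates(monthly, co2 = bundle$co2)
    ens_monthly <- extract_station_series(bundle$ensemble, bundle$stations)
    signal <- acc_signal(ens_monthly,
      baseline = config$baseline,
      window = config$ma_window
    )
    observed <- dplyr::transmute(covars,
      station_id = .data$station_id,
      year = .data$year, t_obs = .data$mat
    )
    acc <- counterfactual(observed, signal)
    write_stage_csv(covars, out_dir, "climate.csv")
    write_stage_csv(acc, out_dir, "counterfactual.csv")
    list(climate = covars, acc = acc)
  })

  # -- stage 4: trend detection ------------------------------------------
  trends <- run_stage("trends", {
    t <- purrr::map(config$metrics, function(m) {
      tidy(detect_trend(metrics, m))
    }) |> purrr::list_rbind()
    write_stage_csv(t, out_dir, "trends.csv")
    t
  })

  # -- stage 5: driver selection (optional) ------------------------------
  selection <- NULL
  if (isTRUE(config$selection$enabled)) {
    selection <- run_stage("selection", {
      data <- dplyr::inner_join(metrics, stage3$climate,
        by = c("station_id", "year")
      )
      s <- all_subsets_selection(data,
        response = config$selection$response,
        predictors = config$selection$predictors,
        aic_window = config$aic_window
      )
      write_stage_csv(s, out_dir, "selection.csv")
      s
    })
  }

  # -- stage 6: ensemble attribution -------------------------------------
  attribution <- run_stage("attribution", {
    a <- ensemble_attribution(
      metrics, stage3$climate, stage3$acc,
      metric_names = config$metrics, periods = config$periods
    )
    write_stage_csv(a, out_dir, "attribution.csv")
    a
  })
  attribution_summary <- summary(attribution)
  write_stage_csv(attribution_summary, out_dir, "attribution_summary.csv")

  # -- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "pollenattrib",
    version = as.character(utils::packageVersion("pollenattrib")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, files)) |>
      setNames(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    bundle = bundle, metrics = metrics, climate = stage3$climate,
    acc = stage3$acc, trends = trends, selection = selection,
    attribution = attribution, attribution_summary = attribution_summary,
    manifest = manifest, out_dir = out_dir
  ))
}
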