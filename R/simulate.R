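# Synthetic station pollen observations, observed climate, and a forced
# climate-model ensemble with planted ground truth. Everything downstream
# (metrics, trend detection, driver selection, attribution) is testable by
# recovering the parameters planted here.

#' Daily pollen emission curve for one station-year
#'
#' Builds a two-lobe (spring-dominant plus fall) seasonal emission curve whose
#' log10 annual sum follows the planted linear temperature response:
#' `log10(sum) = intercept_s + (beta_t + slope_dev_s) * (T - ref_temp_s) +
#' Normal(0, sigma_s)`, where `T` is the station's mean annual temperature and
#' `ref_temp_s` its reference temperature. The spring peak advances by
#' `phenology_shift` days per degree C above the reference temperature. The
#' curve is nonnegative everywhere.
#'
#' Randomness (the lognormal noise on the annual sum) is drawn from the
#' current RNG stream; wrap calls in [withr::with_seed()] or `set.seed()` for
#' reproducibility. Setting the station's `sigma` to 0 in the truth object
#' gives the noise-free curve.
#'
#' @param truth A [truth_params()] object.
#' @param station_id Station identifier present in `truth$stations`.
#' @param year_temperature Mean annual temperature (degrees C) for the year.
#' @param year Calendar year (controls leap-year length).
#' @return A tibble with columns `doy` (1-based day of year) and
#'   `concentration` (grains/m3).
#' @export
#' @examples
#' truth <- truth_params(n_stations = 2, years = 2000:2005, seed = 7)
#' curve <- withr::with_seed(1, generate_daily_emission_curve(
#'   truth, "S001",
#'   year_temperature = truth$stations$ref_temp[1], year = 2001
#' ))
#' sum(curve$concentration) # ~ 10^intercept
generate_daily_emission_curve <- function(truth, station_id, year_temperature,
                                          year = 2001L) {
  stopifnot(inherits(truth, "truth_params"), is.finite(year_temperature))
  st <- truth$stations[truth$stations$station_id == station_id, ]
  if (nrow(st) == 0) {
    abort(sprintf("Unknown station '%s' in truth parameters.", station_id))
  }
  n_days <- days_in_year(year)
  doy <- seq_len(n_days)

  t_anom <- year_temperature - st$ref_temp
  spring_peak <- 105 - truth$phenology_shift * t_anom
  shape <- 0.7 * dnorm(doy, spring_peak, 18) + 0.3 * dnorm(doy, 272, 24)

  log10_sum <- st$intercept + (truth$beta_t + st$slope_dev) * t_anom +
    if (st$sigma > 0) rnorm(1, 0, st$sigma) else 0
  conc <- shape / sum(shape) * 10^log10_sum

  tibble::tibble(doy = doy, concentration = conc)
}

#' Subsample a daily series into irregular pollen records
#'
#' Emulates station convenience sampling: each day is retained independently
#' with probability `1 / sampling_interval_days` (so gaps average the stated
#' interval), and in `"seasonal"` mode days outside a station-specific
#' historical window are dropped entirely, mimicking stations that only
#' operate during their expected pollen season.
#'
#' @param daily Tibble with columns `doy` and `concentration` covering one
#'   full calendar year (output of [generate_daily_emission_curve()]).
#' @param station_id Station identifier to stamp on the records.
#' @param year Calendar year used to build record dates.
#' @param sampling_interval_days Mean gap between measurements (> 0);
#'   1 retains every day.
#' @param mode `"full_year"` samples all year; `"seasonal"` restricts to
#'   `season_window`.
#' @param season_window Length-2 integer day-of-year window (inclusive) for
#'   `"seasonal"` mode.
#' @return Tibble of pollen records: `station_id`, `date`, `concentration`.
#' @export
subsample_to_records <- function(daily, station_id, year,
                                 sampling_interval_days = 2.5,
                                 mode = c("full_year", "seasonal"),
                                 season_window = c(40L, 335L)) {
  mode <- match.arg(mode)
  if (sampling_interval_days <= 0) {
    abort("`sampling_interval_days` must be > 0.")
  }
  stopifnot(all(c("doy", "concentration") %in% names(daily)))
  keep <- runif(nrow(daily)) < min(1, 1 / sampling_interval_days)
  if (mode == "seasonal") {
    keep <- keep & daily$doy >= season_window[1] & daily$doy <= season_window[2]
  }
  out <- daily[keep, ]
  tibble::tibble(
    station_id = station_id,
    date = as.Date(paste0(year, "-01-01")) + out$doy - 1L,
    concentration = out$concentration
  )
}

# Planted anthropogenic warming component: a quadratic ramp from 1850 scaled
# so its OLS linear trend over the analysis years equals
# acc_fraction * (warming / record span), anchored to zero at the analysis
# window center so station temperatures stay near their reference values.
# A quadratic is invariant (up to a constant) under a symmetric moving
# average, so the smoothed ensemble signal recovers the planted trend exactly.
anthro_component <- function(year, truth) {
  yrs <- truth$years
  rate <- truth$warming / diff(range(yrs))
  tt <- yrs - 1850
  coef_t <- stats::cov(tt^2, tt) / stats::var(tt)
  a <- truth$acc_fraction * rate / coef_t
  center <- mean(range(yrs))
  a * ((year - 1850)^2 - (center - 1850)^2)
}

# Natural low-frequency component: slow sinusoid (120-y period) whose
# derivative at the analysis-window center supplies the non-anthropogenic
# remainder of the planted warming trend.
natural_component <- function(year, truth) {
  rate <- truth$warming / diff(range(truth$years))
  rate_nat <- (1 - truth$acc_fraction) * rate
  period <- 120
  center <- mean(range(truth$years))
  rate_nat * period / (2 * pi) * sin(2 * pi * (year - center) / period)
}

# Latitudinal mean-temperature gradient shared by the truth object and the
# gridded generator: warm south (25 degC at 26 N), cold north (~8 degC at 49 N).
base_temp_for_lat <- function(lat) {
  25 - 0.75 * (lat - 26)
}

# Smooth seasonal cycle of monthly temperature (degC), coldest in January.
seasonal_cycle <- function(month, amplitude = 14) {
  -amplitude * cos(2 * pi * (month - 0.5) / 12)
}

# Month-length-weighted annual mean of the seasonal cycle: the constant by
# which a station's mean annual temperature differs from its base temperature.
annual_cycle_offset <- function() {
  stats::weighted.mean(seasonal_cycle(1:12), days_in_month(2001L))
}

#' Synthetic observed climate fields and a forced model ensemble
#'
#' Generates (a) gridded monthly observations (temperature `tas`,
#' precipitation `pr`, frost days `frs`) on the 0.5-degree cells containing
#' the stations, for the analysis years, and (b) an ensemble of climate-model
#' monthly temperature fields spanning 1850 to 25 years past the analysis end
#' (so a centered 50-year moving average is fully covered over the analysis
#' years, and the 1850--1880 anomaly baseline exists).
#'
#' Observed station temperature = planted anthropogenic component
#' (`acc_fraction` of the analysis-window linear trend) + natural
#' low-frequency component + seasonal cycle + white monthly noise. Each
#' ensemble member's forced trajectory = anthropogenic component +
#' model-specific constant bias + white noise, so a moving-average anomaly
#' relative to 1850--1880 recovers the planted anthropogenic trend.
#'
#' @param truth A [truth_params()] object.
#' @param n_models Number of ensemble members (>= 1).
#' @param model_noise_sd SD of white monthly noise in each member (degrees C).
#' @param model_bias_sd SD of the constant per-model bias (degrees C).
#' @return List with tibbles `observed` (`lat, lon, year, month, tas, pr,
#'   frs`) and `ensemble` (`model_id, lat, lon, year, month, tas`).
#' @export
generate_climate_ensemble <- function(truth, n_models = 22,
                                      model_noise_sd = 1.0,
                                      model_bias_sd = 0.5) {
  stopifnot(inherits(truth, "truth_params"))
  if (n_models < 1) abort("`n_models` must be >= 1.")

  cells <- dplyr::distinct(truth$stations, .data$lat, .data$lon)
  cells$base_temp <- base_temp_for_lat(cells$lat)

  obs_years <- truth$years
  obs <- tidyr::expand_grid(
    cells,
    year = obs_years,
    month = 1:12
  )
  obs$tas <- obs$base_temp +
    anthro_component(obs$year, truth) +
    natural_component(obs$year, truth) +
    seasonal_cycle(obs$month) +
    rnorm(nrow(obs), 0, truth$temp_noise_sd)
  obs$pr <- stats::rlnorm(nrow(obs), log(60), 0.4)
  dim_m <- days_in_month(2001L)[obs$month] # frost cap; Feb 28 suffices
  obs$frs <- pmin(dim_m, pmax(0, round((4 - obs$tas) * 3)))
  observed <- tibble::as_tibble(obs[, c(
    "lat", "lon", "year", "month",
    "tas", "pr", "frs"
  )])

  ens_years <- 1850:(max(truth$years) + 25L)
  biases <- rnorm(n_models, 0, model_bias_sd)
  ens <- tidyr::expand_grid(
    model_id = sprintf("M%02d", seq_len(n_models)),
    cells,
    year = ens_years,
    month = 1:12
  )
  ens$tas <- ens$base_temp +
    anthro_component(ens$year, truth) +
    biases[as.integer(sub("M", "", ens$model_id))] +
    seasonal_cycle(ens$month) +
    rnorm(nrow(ens), 0, model_noise_sd)
  ensemble <- tibble::as_tibble(ens[, c(
    "model_id", "lat", "lon", "year",
    "month", "tas"
  )])

  list(observed = observed, ensemble = ensemble)
}

#' Annual atmospheric CO2 concentration series
#'
#' Smooth exponential-growth emulation of the Mauna Loa record
#' (~340 ppm in 1990 rising to ~380 ppm by 2018), identical for all stations.
#'
#' @param years Integer years.
#' @return Tibble with columns `year` and `co2` (ppm).
#' @export
co2_series <- function(years) {
  tibble::tibble(year = as.integer(years), co2 = 280 + 37 * exp((years - 1960) / 60))
}

#' Generate a full synthetic pollen study
#'
#' Runs the whole generator: observed climate and model ensemble on the
#' station grid, then per-station-per-year daily emission curves driven by the
#' station's realized mean annual temperature, subsampled into irregular
#' pollen records. All randomness derives from `truth$seed`, so the same
#' truth object always yields an identical bundle.
#'
#' @param truth A [truth_params()] object.
#' @param n_models Number of climate-model ensemble members.
#' @param sampling_mode Passed to [subsample_to_records()]; the default
#'   `"seasonal"` emulates convenience sampling within a historical window.
#' @param season_window Day-of-year sampling window for `"seasonal"` mode.
#' @param secular_trend Optional temperature-independent multiplicative trend
#'   on pollen: log10 units added per year (default 0). Used to probe
#'   confounding by non-climate trends.
#' @return An object of class `pollen_bundle`: list with `records` (pollen
#'   records), `stations`, `observed_climate`, `ensemble`, `co2`, `truth`.
#' @export
#' @examples
#' truth <- truth_params(n_stations = 3, years = 2000:2006, seed = 42)
#' bundle <- simulate_pollen_study(truth, n_models = 2)
#' bundle$records
simulate_pollen_study <- function(truth, n_models = 22,
                                  sampling_mode = c("seasonal", "full_year"),
                                  season_window = c(40L, 335L),
                                  secular_trend = 0) {
  stopifnot(inherits(truth, "truth_params"))
  sampling_mode <- match.arg(sampling_mode)

  clim <- withr::with_seed(
    stage_seed(truth$seed, 1L),
    generate_climate_ensemble(truth, n_models = n_models)
  )
  monthly <- extract_station_series(clim$observed, truth$stations)
  mat <- annual_mean_temperature(monthly)

  records <- withr::with_seed(stage_seed(truth$seed, 2L), {
    purrr::pmap(
      mat,
      function(station_id, year, mat) {
        daily <- generate_daily_emission_curve(truth, station_id, mat, year)
        if (secular_trend != 0) {
          daily$concentration <- daily$concentration *
            10^(secular_trend * (year - min(truth$years)))
        }
        subsample_to_records(
          daily, station_id, year,
          sampling_interval_days = truth$sampling_interval_days,
          mode = sampling_mode, season_window = season_window
        )
      }
    ) |> purrr::list_rbind()
  })

  structure(
    list(
      records = records,
      stations = truth$stations,
      observed_climate = clim$observed,
      ensemble = clim$ensemble,
      co2 = co2_series(1850:(max(truth$years) + 25L)),
      truth = truth,
      sampling_mode = sampling_mode,
      season_window = season_window
    ),
    class = "pollen_bundle"
  )
}

#' @export
print.pollen_bundle <- function(x, ...) {
  cat("<pollen_bundle>\n")
  cat(sprintf(
    "  %d records, %d stations, years %d-%d\n",
    nrow(x$records), nrow(x$stations),
    min(x$truth$years), max(x$truth$years)
  ))
  cat(sprintf(
    "  ensemble: %d models, %d-%d\n",
    dplyr::n_distinct(x$ensemble$model_id),
    min(x$ensemble$year), max(x$ensemble$year)
  ))
  invisible(x)
}

#' Simulate a station-by-year metric panel from the trend model itself
#'
#' Draws directly from the heteroscedastic random-slope data-generating
#' process used for trend detection: on the transformed scale,
#' `g(y) = b0_s + b1_s * (year - year0) + Normal(0, sigma_s)` with
#' station-level `b0_s ~ N(intercept_mean, intercept_sd)`,
#' `b1_s ~ N(slope, slope_sd)`, and `sigma_s ~ U(sigma_range)`. Values are
#' returned back-transformed to the natural scale. Useful for targeted
#' parameter-recovery and coverage experiments on the model machinery without
#' running the full emission-curve generator.
#'
#' @param n_stations,years Panel dimensions.
#' @param slope Planted fixed-effect slope per year on the transformed scale.
#' @param slope_sd,intercept_mean,intercept_sd,sigma_range Station-level
#'   parameter distributions (see above).
#' @param transform Transformation linking the natural metric scale to the
#'   linear model scale: values are back-transformed with `10^x` for
#'   `"log10"`, `x^2` for `"sqrt"`, identity for `"none"`.
#' @param metric Name of the metric column in the output.
#' @return Tibble: `station_id`, `year`, and one metric column
#'   (natural scale).
#' @export
simulate_metric_panel <- function(n_stations = 60, years = 1990:2018,
                                  slope = 0.00285, slope_sd = 0.001,
                                  intercept_mean = 3.8, intercept_sd = 0.35,
                                  sigma_range = c(0.05, 0.15),
                                  transform = c("log10", "sqrt", "none"),
                                  metric = "annual_integral") {
  transform <- match.arg(transform)
  b0 <- rnorm(n_stations, intercept_mean, intercept_sd)
  b1 <- rnorm(n_stations, slope, slope_sd)
  sig <- runif(n_stations, sigma_range[1], sigma_range[2])
  panel <- tidyr::expand_grid(s = seq_len(n_stations), year = as.integer(years))
  g <- b0[panel$s] + b1[panel$s] * (panel$year - min(years)) +
    rnorm(nrow(panel), 0, sig[panel$s])
  y <- switch(transform,
    log10 = 10^g,
    sqrt = g^2,
    none = g
  )
  tibble::tibble(
    station_id = sprintf("S%03d", panel$s),
    year = panel$year,
    !!metric := y
  )
}
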