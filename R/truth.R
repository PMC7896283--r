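#' Ground-truth parameters for the synthetic pollen study
#'
#' Defines the planted truth that the synthetic-data generator embeds and the
#' downstream pipeline must recover: a global temperature sensitivity of the
#' (log10) annual pollen integral, station-level deviations around it, a
#' phenological advance of the season start per degree of warming, and the
#' fraction of the observed warming trend that is anthropogenic.
#'
#' Defaults emulate the observed study conditions for North American pollen
#' stations over 1990--2018: 60 stations, about 1 degree C of warming over the
#' record, a temperature sensitivity such that 1 degree C of warming raises
#' the annual pollen integral by roughly 21 percent
#' (`beta_t = log10(1.21) ~= 0.0828` log10 units per degree C), a season-start
#' advance of about 20 days per degree C, and measurements on average every
#' 2.5 days.
#'
#' @param n_stations Number of pollen stations.
#' @param years Analysis years (integer vector, within 1850--2100).
#' @param beta_t Global fixed effect: change in log10 annual pollen integral
#'   per degree C of mean annual temperature.
#' @param slope_sd Standard deviation of per-station deviations from `beta_t`.
#' @param intercept_mean,intercept_sd Mean and SD of per-station baseline
#'   log10 annual integrals (log10 grains day/m3).
#' @param sigma_range Range from which per-station residual SDs (log10 scale)
#'   are drawn uniformly; both endpoints must be positive.
#' @param phenology_shift Advance of the spring emission peak, in days per
#'   degree C above the station's reference temperature.
#' @param acc_fraction Fraction of the observed 1990-to-end linear
#'   temperature trend that is anthropogenic (in [0, 1]).
#' @param warming Planted total linear warming (degrees C) over `years`.
#' @param temp_noise_sd SD of white monthly temperature noise (degrees C);
#'   the implied interannual noise on mean annual temperature is about
#'   `temp_noise_sd / sqrt(12)`.
#' @param sampling_interval_days Mean gap between pollen measurements (days).
#' @param seed Integer seed; the same seed yields an identical truth object
#'   and, through [simulate_pollen_study()], an identical synthetic bundle.
#'
#' @return An object of class `truth_params`: a list with the scalar
#'   parameters above plus a `stations` tibble (station_id, lat, lon,
#'   ref_temp, slope_dev, intercept, sigma) with coordinates snapped to
#'   0.5-degree grid-cell centers.
#' @export
#' @examples
#' truth <- truth_params(n_stations = 5, years = 2000:2010, seed = 1)
#' truth$stations
truth_params <- function(n_stations = 60,
                         years = 1990:2018,
                         beta_t = log10(1.21),
                         slope_sd = 0.015,
                         intercept_mean = 3.8,
                         intercept_sd = 0.35,
                         sigma_range = c(0.05, 0.15),
                         phenology_shift = 20,
                         acc_fraction = 0.75,
                         warming = 1.0,
                         temp_noise_sd = 1.0,
                         sampling_interval_days = 2.5,
                         seed = 1L) {
  stopifnot(n_stations >= 1, length(years) >= 2)
  years <- sort(as.integer(years))
  if (min(years) < 1850 || max(years) > 2100) {
    abort("`years` must lie within [1850, 2100].")
  }
  if (any(sigma_range <= 0)) {
    abort("`sigma_range` must be positive: station residual SDs must be > 0.")
  }
  if (acc_fraction < 0 || acc_fraction > 1) {
    abort("`acc_fraction` must lie in [0, 1].")
  }
  if (sampling_interval_days <= 0) {
    abort("`sampling_interval_days` must be > 0.")
  }

  stations <- withr::with_seed(seed, {
    lat <- snap_half_degree(runif(n_stations, 26, 49))
    lon <- snap_half_degree(runif(n_stations, -124, -71))
    # warmer south, cooler north; deterministic given coordinates.
    # The offset makes ref_temp the station's expected mean annual
    # temperature (month-length-weighted) at the analysis-window center.
    ref_temp <- base_temp_for_lat(lat) + annual_cycle_offset()
    tibble::tibble(
      station_id = sprintf("S%03d", seq_len(n_stations)),
      lat = lat,
      lon = lon,
      ref_temp = ref_temp,
      slope_dev = rnorm(n_stations, 0, slope_sd),
      # station baselines follow the planted sensitivity along the spatial
      # temperature gradient, so pollen responds to temperature consistently
      # in space and in time
      intercept = rnorm(n_stations, intercept_mean, intercept_sd) +
        beta_t * (ref_temp - mean(ref_temp)),
      sigma = runif(n_stations, sigma_range[1], sigma_range[2])
    )
  })

  structure(
    list(
      n_stations = n_stations,
      years = years,
      beta_t = beta_t,
      slope_sd = slope_sd,
      intercept_mean = intercept_mean,
      intercept_sd = intercept_sd,
      sigma_range = sigma_range,
      phenology_shift = phenology_shift,
      acc_fraction = acc_fraction,
      warming = warming,
      temp_noise_sd = temp_noise_sd,
      sampling_interval_days = sampling_interval_days,
      seed = as.integer(seed),
      stations = stations
    ),
    class = "truth_params"
  )
}

# Snap coordinates to 0.5-degree cell centers (x.25 / x.75), mirroring
# station-to-grid matching on a half-degree observational grid.
snap_half_degree <- function(x) {
  floor(x * 2) / 2 + 0.25
}

#' @export
print.truth_params <- function(x, ...) {
  cat("<truth_params>\n")
  cat(sprintf(
    "  %d stations, years %d-%d\n", x$n_stations,
    min(x$years), max(x$years)
  ))
  cat(sprintf(
    "  beta_t = %.4f log10/degC (+/- %.3f across stations)\n",
    x$beta_t, x$slope_sd
  ))
  cat(sprintf(
    "  warming = %.2f degC over record, acc_fraction = %.2f\n",
    x$warming, x$acc_fraction
  ))
  cat(sprintf(
    "  phenology_shift = %.1f d/degC, sampling every %.1f d\n",
    x$phenology_shift, x$sampling_interval_days
  ))
  invisible(x)
}
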