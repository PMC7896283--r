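# Climate processing: station extraction from gridded fields, annual
# covariates, the ensemble anthropogenic (ACC) signal, and the counterfactual
# no-ACC temperature series.

#' Extract per-station monthly series from a gridded field
#'
#' Matches each station to the nearest grid-cell center and returns the cell's
#' monthly values stamped with the station id. Works for any gridded tibble
#' with `lat`/`lon` columns (observations or an ensemble with a `model_id`
#' column: extra columns are carried through).
#'
#' @param grid Tibble of gridded values with columns `lat`, `lon` and any
#'   value/time columns.
#' @param stations Tibble with columns `station_id`, `lat`, `lon`.
#' @param max_dist Maximum allowed degrees (Chebyshev distance) between a
#'   station and its nearest cell center before the station is declared
#'   outside the grid.
#' @return Tibble: `station_id` plus all non-coordinate columns of `grid`.
#' @export
extract_station_series <- function(grid, stations, max_dist = 0.5) {
  stopifnot(all(c("lat", "lon") %in% names(grid)),
            all(c("station_id", "lat", "lon") %in% names(stations)))
  cells <- dplyr::distinct(grid, .data$lat, .data$lon)
  match_one <- function(station_id, lat, lon) {
    d <- pmax(abs(cells$lat - lat), abs(cells$lon - lon))
    i <- which.min(d)
    if (d[i] > max_dist) {
      abort(sprintf(
        "Station '%s' (%.2f, %.2f) lies outside the climate grid.",
        station_id, lat, lon
      ))
    }
    tibble::tibble(station_id = station_id, lat = cells$lat[i], lon = cells$lon[i])
  }
  key <- purrr::pmap(
    stations[, c("station_id", "lat", "lon")], match_one
  ) |> purrr::list_rbind()
  out <- dplyr::inner_join(key, grid, by = c("lat", "lon"),
                           relationship = "many-to-many")
  dplyr::select(out, -"lat", -"lon")
}

# Month-length-weighted annual mean temperature per station-year.
annual_mean_temperature <- function(monthly) {
  monthly |>
    dplyr::group_by(.data$station_id, .data$year) |>
    dplyr::summarise(
      mat = stats::weighted.mean(.data$tas, days_in_month(.data$year[1])[.data$month]),
      .groups = "drop"
    )
}

#' Annual and seasonal climate covariates per station-year
#'
#' Reduces per-station monthly series to the eight climate covariates used as
#' candidate drivers of pollen metrics, plus atmospheric CO2: mean annual
#' temperature (`mat`), total annual precipitation (`map`), mean spring
#' (February--May) and summer (June--August) temperature (`spring_t`,
#' `summer_t`), total spring/summer precipitation (`spring_p`, `summer_p`),
#' and spring/summer frost-day counts (`spring_frost`, `summer_frost`).
#' Temperature means are weighted by month length; precipitation and frost
#' days are summed. Years with any missing month yield missing covariates.
#'
#' @param monthly Tibble with `station_id`, `year`, `month`, `tas`, `pr`,
#'   `frs` (output of [extract_station_series()] on observations).
#' @param co2 Optional tibble `year`, `co2` (ppm), identical across stations;
#'   joined by year when supplied.
#' @return Tibble of station-year covariates.
#' @export
annual_covariates <- function(monthly, co2 = NULL) {
  need <- c("station_id", "year", "month", "tas", "pr", "frs")
  stopifnot(all(need %in% names(monthly)))
  df <- tibble::as_tibble(monthly)
  # month-length weights, leap-aware
  base <- days_in_month(2001L)
  df$w <- ifelse(df$month == 2L & is_leap_year(df$year), 29L, base[df$month])
  df$sp <- df$month %in% CLIMATE_SPRING_MONTHS
  df$su <- df$month %in% CLIMATE_SUMMER_MONTHS
  out <- df |>
    dplyr::group_by(.data$station_id, .data$year) |>
    dplyr::summarise(
      n_months = dplyr::n_distinct(.data$month),
      mat = sum(.data$tas * .data$w) / sum(.data$w),
      map = sum(.data$pr),
      spring_t = sum(.data$tas[.data$sp] * .data$w[.data$sp]) /
        sum(.data$w[.data$sp]),
      spring_p = sum(.data$pr[.data$sp]),
      spring_frost = sum(.data$frs[.data$sp]),
      summer_t = sum(.data$tas[.data$su] * .data$w[.data$su]) /
        sum(.data$w[.data$su]),
      summer_p = sum(.data$pr[.data$su]),
      summer_frost = sum(.data$frs[.data$su]),
      .groups = "drop"
    )
  vars <- c(
    "mat", "map", "spring_t", "spring_p", "spring_frost",
    "summer_t", "summer_p", "summer_frost"
  )
  incomplete <- out$n_months < 12L
  out[incomplete, vars] <- NA_real_
  out$n_months <- NULL
  if (!is.null(co2)) {
    out <- dplyr::left_join(out, co2[, c("year", "co2")], by = "year")
  }
  out
}

#' Anthropogenic climate change signal from a model ensemble
#'
#' For each ensemble member and station (or grid cell), computes annual mean
#' temperature, subtracts the member's 1850--1880 climatology to obtain
#' anomalies, and smooths them with a centered 50-year moving average to
#' remove internal variability, leaving the forced (anthropogenic) signal.
#' Where the series ends within half a window of an edge, the window shrinks
#' symmetrically rather than padding.
#'
#' @param ensemble_monthly Tibble `model_id`, `station_id`, `year`, `month`,
#'   `tas` (an ensemble passed through [extract_station_series()]).
#' @param baseline Two years bounding the anomaly climatology (inclusive).
#' @param window Moving-average window in years (symmetric half-width
#'   `floor(window/2)`).
#' @return Tibble `model_id`, `station_id`, `year`, `acc_anomaly` (degC).
#' @export
acc_signal <- function(ensemble_monthly, baseline = c(1850, 1880), window = 50) {
  stopifnot(all(c("model_id", "station_id", "year", "month", "tas") %in%
                  names(ensemble_monthly)))
  if (min(ensemble_monthly$year) > baseline[1]) {
    abort(sprintf(
      "Ensemble series starts at %d and does not span the %d-%d baseline.",
      min(ensemble_monthly$year), baseline[1], baseline[2]
    ))
  }
  annual <- ensemble_monthly |>
    dplyr::group_by(.data$model_id, .data$station_id, .data$year) |>
    dplyr::summarise(
      tann = stats::weighted.mean(.data$tas, days_in_month(.data$year[1])[.data$month]),
      .groups = "drop"
    )
  annual |>
    dplyr::group_by(.data$model_id, .data$station_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(
      acc_anomaly = centered_ma(
        .data$tann - mean(.data$tann[.data$year >= baseline[1] &
                                       .data$year <= baseline[2]]),
        window
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select("model_id", "station_id", "year", "acc_anomaly")
}

#' Counterfactual no-ACC temperature series
#'
#' Subtracts each model's anthropogenic signal from the observed station
#' temperatures: `t_no_acc = t_with_acc - acc_anomaly`, one series per
#' (model, station). This is the temperature the station would have seen in a
#' world without anthropogenic forcing, as estimated by that model.
#'
#' @param observed Tibble `station_id`, `year`, `t_obs` (observed mean annual
#'   temperature; see [annual_mean_temperature] via [annual_covariates()]'s
#'   `mat`).
#' @param acc Output of [acc_signal()] restricted (or restrictable) to the
#'   observed years; every observed (station, year) must be present for every
#'   model.
#' @return Tibble `model_id`, `station_id`, `year`, `acc_anomaly`,
#'   `t_with_acc`, `t_no_acc`.
#' @export
counterfactual <- function(observed, acc) {
  stopifnot(all(c("station_id", "year", "t_obs") %in% names(observed)),
            all(c("model_id", "station_id", "year", "acc_anomaly") %in% names(acc)))
  out <- dplyr::inner_join(observed, acc, by = c("station_id", "year"),
                           relationship = "many-to-many")
  n_models <- dplyr::n_distinct(acc$model_id)
  if (nrow(out) != nrow(observed) * n_models) {
    abort(paste0(
      "Observed years and ACC-signal years are misaligned: every observed ",
      "(station, year) must be covered by every model."
    ))
  }
  out |>
    dplyr::transmute(
      model_id = .data$model_id,
      station_id = .data$station_id,
      year = .data$year,
      acc_anomaly = .data$acc_anomaly,
      t_with_acc = .data$t_obs,
      t_no_acc = .data$t_obs - .data$acc_anomaly
    ) |>
    dplyr::arrange(.data$model_id, .data$station_id, .data$year)
}
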