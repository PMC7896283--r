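# Pollen-season metrics: QC/inclusion rules, daily interpolation, the ten
# per-station-per-year metrics, and sampling-bias diagnostics.
#
# The numeric kernels (k_*) operate on plain vectors and are shared between
# the exported single-series functions and the vectorized pollen_metrics()
# pipeline, so both paths compute identically.

# Linear interpolation of (doy, concentration) measurements onto every day
# between the first and last measurement. No extrapolation.
k_interp <- function(doy, conc) {
  ord <- order(doy)
  doy <- doy[ord]
  conc <- conc[ord]
  grid <- seq(doy[1], doy[length(doy)])
  list(doy = grid, conc = approx(doy, conc, xout = grid, method = "linear")$y)
}

k_stats <- function(conc) {
  c(max = max(conc), mean = mean(conc), median = median(conc))
}

# First/last day strictly above the threshold; NA when never exceeded.
k_season <- function(doy, conc, threshold) {
  over <- doy[conc > threshold]
  if (length(over) == 0) {
    return(c(start = NA_integer_, end = NA_integer_, length = NA_integer_))
  }
  s <- min(over)
  e <- max(over)
  c(start = s, end = e, length = e - s + 1L)
}

# Seasonal/annual sums over covered days; empty windows give 0.
k_integrals <- function(doy, conc, year) {
  win <- season_windows(year)
  one <- function(w) sum(conc[doy >= w["start"] & doy <= w["end"]])
  c(
    spring = one(win$spring), summer = one(win$summer),
    fall = one(win$fall), annual = one(win$annual)
  )
}

#' Inclusion rules for station pollen records
#'
#' Applies the study's a priori criteria: a station-year is retained only if
#' it holds at least `min_measurements` measurements, and a station is
#' retained only if at least `min_years` of its years survive. Duplicate
#' records for the same (station, date) are averaged first (with a warning).
#'
#' @param records Tibble of pollen records: `station_id`, `date` (Date),
#'   `concentration` (grains/m3, >= 0).
#' @param min_measurements Minimum measurements per station-year (default 10).
#' @param min_years Minimum retained years per station (default 5).
#' @return List with `records` (retained, de-duplicated records) and
#'   `exclusions` (tibble `station_id`, `year` (NA for station-level drops),
#'   `rule`) naming every dropped unit.
#' @export
qc_filter <- function(records, min_measurements = 10, min_years = 5) {
  records <- check_records(records)
  if (nrow(records) == 0) abort("no records")
  records <- dedupe_records(records)
  records$year <- as.integer(format(records$date, "%Y"))

  counts <- dplyr::count(records, .data$station_id, .data$year)
  bad_years <- counts[counts$n < min_measurements, ]
  excl <- tibble::tibble(
    station_id = bad_years$station_id,
    year = bad_years$year,
    rule = sprintf("fewer than %d measurements in year", min_measurements)
  )
  kept <- dplyr::anti_join(records, bad_years, by = c("station_id", "year"))

  year_counts <- dplyr::count(dplyr::distinct(kept, .data$station_id, .data$year),
                              .data$station_id)
  bad_stations <- year_counts$station_id[year_counts$n < min_years]
  # stations whose every year was dropped also fail the min-years rule
  all_st <- unique(records$station_id)
  bad_stations <- union(bad_stations, setdiff(all_st, year_counts$station_id))
  excl <- dplyr::bind_rows(excl, tibble::tibble(
    station_id = bad_stations,
    year = NA_integer_,
    rule = sprintf("fewer than %d retained years", min_years)
  ))
  kept <- kept[!kept$station_id %in% bad_stations, ]
  list(
    records = dplyr::select(kept, -"year"),
    exclusions = excl
  )
}

check_records <- function(records) {
  need <- c("station_id", "date", "concentration")
  if (!all(need %in% names(records))) {
    abort("`records` needs columns station_id, date, concentration.")
  }
  if (any(!is.finite(records$concentration)) || any(records$concentration < 0)) {
    abort("Concentrations must be finite and >= 0.")
  }
  records$date <- as.Date(records$date)
  tibble::as_tibble(records)
}

dedupe_records <- function(records) {
  dup <- duplicated(records[, c("station_id", "date")])
  if (any(dup)) {
    warn(sprintf(
      "%d duplicate (station, date) records averaged.", sum(dup)
    ))
    records <- records |>
      dplyr::group_by(.data$station_id, .data$date) |>
      dplyr::summarise(concentration = mean(.data$concentration), .groups = "drop")
  }
  records
}

#' Per-station season thresholds from raw measurements
#'
#' The pollen-season threshold for a station is a percentile (default 30th)
#' of its raw daily concentration measurements. By default measurements are
#' pooled across all of the station's years; `pooled = FALSE` computes a
#' within-year threshold instead. Percentiles use linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param records De-duplicated pollen records.
#' @param percentile Percentile in [0, 100] (default 30).
#' @param pooled Pool measurements across years (default) or per year.
#' @return Tibble `station_id` (+ `year` if `pooled = FALSE`), `threshold`.
#' @export
station_thresholds <- function(records, percentile = 30, pooled = TRUE) {
  stopifnot(percentile >= 0, percentile <= 100)
  records <- check_records(records)
  if (pooled) {
    records |>
      dplyr::group_by(.data$station_id) |>
      dplyr::summarise(
        threshold = quantile(.data$concentration, percentile / 100,
                             type = 7, names = FALSE),
        .groups = "drop"
      )
  } else {
    records |>
      dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
      dplyr::group_by(.data$station_id, .data$year) |>
      dplyr::summarise(
        threshold = quantile(.data$concentration, percentile / 100,
                             type = 7, names = FALSE),
        .groups = "drop"
      )
  }
}

#' Linear interpolation of one station-year to a daily series
#'
#' Interpolates 24-h concentration measurements linearly over the course of
#' the year: daily values on every calendar day between the first and last
#' measurement, reproducing measured values exactly on measured days. Days
#' before the first or after the last measurement are absent (never
#' extrapolated). Interpolation does not cross calendar-year boundaries.
#'
#' @param records Records for a single station-year (>= 2 rows).
#' @return Tibble `doy` (1-based day of year), `date`, `concentration`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   station_id = "A",
#'   date = as.Date(c("2001-01-10", "2001-01-12")),
#'   concentration = c(100, 200)
#' )
#' interpolate_daily(rec) # day 11 = 150
interpolate_daily <- function(records) {
  records <- check_records(records)
  if (length(unique(format(records$date, "%Y"))) > 1) {
    abort("interpolate_daily() expects records from a single calendar year.")
  }
  if (nrow(records) < 2) {
    abort("Cannot interpolate: fewer than 2 measurements in the year.")
  }
  records <- dedupe_records(records)
  year <- as.integer(format(records$date[1], "%Y"))
  jan1 <- as.Date(paste0(year, "-01-01"))
  doy <- as.integer(records$date - jan1) + 1L
  daily <- k_interp(doy, records$concentration)
  tibble::tibble(
    doy = daily$doy, date = jan1 + daily$doy - 1L,
    concentration = daily$conc
  )
}

#' Pollen season bounds from a daily series
#'
#' The season starts on the first day of the calendar year on which the daily
#' concentration exceeds the station threshold, and ends on the last day it
#' exceeds the threshold; length is inclusive. If no day exceeds the
#' threshold the season is missing (NA), not zero.
#'
#' @param daily Daily series (tibble `doy`, `concentration`), typically from
#'   [interpolate_daily()].
#' @param threshold Station season threshold (see [station_thresholds()]).
#' @return Tibble with one row: `start_doy`, `end_doy`, `season_length`.
#' @export
season_bounds <- function(daily, threshold) {
  stopifnot(all(c("doy", "concentration") %in% names(daily)), nrow(daily) > 0)
  b <- k_season(daily$doy, daily$concentration, threshold)
  tibble::tibble(
    start_doy = as.integer(b["start"]), end_doy = as.integer(b["end"]),
    season_length = as.integer(b["length"])
  )
}

#' Seasonal and annual pollen integrals
#'
#' Sums daily concentrations over the calendar windows spring (Feb 1--May 31),
#' summer (Jun 1--Aug 31), fall (Sep 1--Nov 30), and the full calendar year,
#' leap-aware, counting only days the series covers. An integral over a
#' window with no covered days is 0, with a coverage warning.
#'
#' @param daily Daily series (tibble `doy`, `concentration`) for one
#'   station-year.
#' @param year Calendar year of the series (controls leap windows). If the
#'   series has a `date` column the year is taken from it.
#' @return Tibble with one row: `spring_integral`, `summer_integral`,
#'   `fall_integral`, `annual_integral` (grains day/m3).
#' @export
seasonal_integrals <- function(daily, year = NULL) {
  stopifnot(all(c("doy", "concentration") %in% names(daily)))
  if (is.null(year)) {
    if (!"date" %in% names(daily)) {
      abort("Provide `year` or a `date` column.")
    }
    year <- as.integer(format(daily$date[1], "%Y"))
  }
  win <- season_windows(year)
  for (w in win[c("spring", "summer", "fall")]) {
    if (!any(daily$doy >= w["start"] & daily$doy <= w["end"])) {
      warn(sprintf(
        "No covered days in window %d-%d; integral set to 0.",
        w["start"], w["end"]
      ))
    }
  }
  v <- k_integrals(daily$doy, daily$concentration, year)
  tibble::tibble(
    spring_integral = unname(v["spring"]),
    summer_integral = unname(v["summer"]),
    fall_integral = unname(v["fall"]),
    annual_integral = unname(v["annual"])
  )
}

#' Daily concentration statistics
#'
#' Maximum, mean, and median of the daily concentrations over the days the
#' series covers.
#'
#' @param daily Daily series (tibble with `concentration`).
#' @return Tibble with one row: `max_daily`, `mean_daily`, `median_daily`.
#' @export
daily_stats <- function(daily) {
  stopifnot("concentration" %in% names(daily), nrow(daily) > 0)
  tibble::tibble(
    max_daily = max(daily$concentration),
    mean_daily = mean(daily$concentration),
    median_daily = median(daily$concentration)
  )
}

#' Flag station-years that may have missed the season start
#'
#' TRUE when the first measurement of the station-year already exceeds the
#' station's season threshold, indicating sampling may have begun after the
#' true start of the pollen season.
#'
#' @param records Records for one station-year.
#' @param threshold Station season threshold.
#' @return Logical scalar.
#' @export
flag_missed_start <- function(records, threshold) {
  records <- check_records(records)
  first <- records$concentration[which.min(records$date)]
  first > threshold
}

#' Compute the ten pollen metrics for every station-year
#'
#' Full metrics pipeline: inclusion rules ([qc_filter()]), per-station season
#' thresholds ([station_thresholds()]), daily linear interpolation
#' ([interpolate_daily()]), then per station-year the daily statistics
#' (maximum, mean, median), season bounds and length, seasonal and annual
#' integrals, the measurement count, and the missed-start flag. Station-years
#' whose interpolated series never exceeds the threshold get missing season
#' metrics; metrics are never imputed.
#'
#' @inheritParams qc_filter
#' @inheritParams station_thresholds
#' @param qc Apply inclusion rules first (default TRUE).
#' @return Tibble with one row per retained station-year: `station_id`,
#'   `year`, `max_daily`, `mean_daily`, `median_daily`, `start_doy`,
#'   `end_doy`, `season_length`, `spring_integral`, `summer_integral`,
#'   `fall_integral`, `annual_integral`, `n_measurements`,
#'   `flag_missed_start`. The QC exclusion log is attached as attribute
#'   `"exclusions"`.
#' @export
#' @examples
#' truth <- truth_params(n_stations = 2, years = 2000:2005, seed = 3)
#' bundle <- simulate_pollen_study(truth, n_models = 1)
#' metrics <- pollen_metrics(bundle$records)
#' metrics
pollen_metrics <- function(records, percentile = 30, pooled = TRUE,
                           min_measurements = 10, min_years = 5, qc = TRUE) {
  if (qc) {
    filtered <- qc_filter(records, min_measurements, min_years)
    records <- filtered$records
    exclusions <- filtered$exclusions
  } else {
    records <- dedupe_records(check_records(records))
    exclusions <- tibble::tibble(
      station_id = character(), year = integer(), rule = character()
    )
  }
  if (nrow(records) == 0) abort("no records survive the inclusion rules")
  thresholds <- station_thresholds(records, percentile, pooled = pooled)

  records$year <- as.integer(format(records$date, "%Y"))
  records$doy <- as.integer(
    records$date - as.Date(paste0(records$year, "-01-01"))
  ) + 1L
  records <- records[order(records$station_id, records$date), ]

  groups <- split(
    seq_len(nrow(records)),
    list(records$station_id, records$year),
    drop = TRUE, sep = "\r"
  )
  thr_lookup <- function(st, yr) {
    if (pooled) {
      thresholds$threshold[thresholds$station_id == st]
    } else {
      thresholds$threshold[thresholds$station_id == st & thresholds$year == yr]
    }
  }
  rows <- purrr::map(groups, function(idx) {
    st <- records$station_id[idx[1]]
    yr <- records$year[idx[1]]
    thr <- thr_lookup(st, yr)
    conc <- records$concentration[idx]
    n <- length(idx)
    if (n < 2) {
      return(c(rep(NA_real_, 10), n, NA))
    }
    daily <- k_interp(records$doy[idx], conc)
    c(
      k_stats(daily$conc),
      k_season(daily$doy, daily$conc, thr),
      k_integrals(daily$doy, daily$conc, yr),
      n,
      conc[1] > thr # records are date-ordered within group
    )
  })
  mat <- do.call(rbind, rows)
  key <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- tibble::tibble(
    station_id = key[, 1],
    year = as.integer(key[, 2]),
    max_daily = mat[, 1],
    mean_daily = mat[, 2],
    median_daily = mat[, 3],
    start_doy = as.integer(mat[, 4]),
    end_doy = as.integer(mat[, 5]),
    season_length = as.integer(mat[, 6]),
    spring_integral = mat[, 7],
    summer_integral = mat[, 8],
    fall_integral = mat[, 9],
    annual_integral = mat[, 10],
    n_measurements = as.integer(mat[, 11]),
    flag_missed_start = as.logical(mat[, 12])
  )
  out <- out[order(out$station_id, out$year), ]
  attr(out, "exclusions") <- exclusions
  out
}

#' Test for systematic sampling bias between record halves
#'
#' Splits each station's years chronologically into a first and second half
#' (odd counts: the middle year joins the first half) and compares, between
#' halves, the distribution of (a) the first measurement's concentration and
#' (b) the mean of the first five measurements of each year, with Wilcoxon
#' rank-sum tests. A widespread pattern of missing the season start early in
#' the record would show up as a shift. Per-station z-scores are pooled
#' across stations by Stouffer's method.
#'
#' @param records Pollen records (several stations, >= `min_years_test` years
#'   each; stations with fewer years are dropped with a message).
#' @param min_years_test Minimum years for a station to be testable
#'   (default 6).
#' @return List with `by_station` (tibble `station_id`, `test`, `statistic`,
#'   `p_value`) and `pooled` (tibble `test`, `z`, `p_value`).
#' @export
sampling_bias_test <- function(records, min_years_test = 6) {
  records <- dedupe_records(check_records(records))
  records$year <- as.integer(format(records$date, "%Y"))

  per_year <- records |>
    dplyr::arrange(.data$station_id, .data$date) |>
    dplyr::group_by(.data$station_id, .data$year) |>
    dplyr::summarise(
      first_measurement = .data$concentration[1],
      first_five_mean = mean(head(.data$concentration, 5)),
      .groups = "drop"
    )
  usable <- per_year |>
    dplyr::count(.data$station_id) |>
    dplyr::filter(.data$n >= min_years_test)
  dropped <- dplyr::n_distinct(per_year$station_id) - nrow(usable)
  if (dropped > 0) {
    inform(sprintf("%d station(s) with < %d years skipped.", dropped,
                   min_years_test))
  }
  if (nrow(usable) == 0) abort("No station has enough years to test.")
  per_year <- dplyr::semi_join(per_year, usable, by = "station_id")

  test_one <- function(x, half) {
    w <- suppressWarnings(wilcox.test(x[half == 1], x[half == 2], exact = FALSE))
    n1 <- sum(half == 1); n2 <- sum(half == 2)
    z <- (unname(w$statistic) - n1 * n2 / 2) /
      sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value, z = z)
  }
  by_station <- per_year |>
    dplyr::group_by(.data$station_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      half <- ifelse(seq_len(nrow(df)) <= ceiling(nrow(df) / 2), 1L, 2L)
      dplyr::bind_rows(
        dplyr::mutate(test_one(df$first_measurement, half),
                      test = "first_measurement"),
        dplyr::mutate(test_one(df$first_five_mean, half),
                      test = "first_five_mean")
      )
    }) |>
    dplyr::ungroup()

  pooled <- by_station |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(
      z = sum(.data$z) / sqrt(dplyr::n()),
      p_value = 2 * pnorm(-abs(.data$z)),
      .groups = "drop"
    )
  list(
    by_station = dplyr::select(by_station, "station_id", "test", "statistic",
                               "p_value"),
    pooled = pooled
  )
}
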