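# Shared internal helpers: calendar arithmetic and seasonal date windows.

#' Days in each month of a year
#'
#' @param year Calendar year (leap-aware).
#' @return Integer vector of length 12.
#' @keywords internal
days_in_month <- function(year) {
  feb <- ifelse(is_leap_year(year), 29L, 28L)
  out <- c(31L, feb, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

days_in_year <- function(year) ifelse(is_leap_year(year), 366L, 365L)

#' Day-of-year bounds of a calendar-date window
#'
#' Converts a (month, day)--(month, day) closed window into 1-based
#' day-of-year bounds for a given year, respecting leap years.
#' @keywords internal
doy_window <- function(year, from_month, from_day, to_month, to_day) {
  cum <- c(0L, cumsum(days_in_month(year)))
  c(
    start = cum[from_month] + from_day,
    end = cum[to_month] + to_day
  )
}

# Seasonal windows used for pollen integrals (calendar dates):
# spring Feb 1 - May 31, summer Jun 1 - Aug 31, fall Sep 1 - Nov 30.
season_windows <- function(year) {
  list(
    spring = doy_window(year, 2L, 1L, 5L, 31L),
    summer = doy_window(year, 6L, 1L, 8L, 31L),
    fall = doy_window(year, 9L, 1L, 11L, 30L),
    annual = c(start = 1L, end = days_in_year(year))
  )
}

# Months defining seasonal climate covariates: spring Feb-May, summer Jun-Aug.
CLIMATE_SPRING_MONTHS <- 2:5
CLIMATE_SUMMER_MONTHS <- 6:8

#' Centered moving average with symmetric edge shrinkage
#'
#' Smooths `x` with a symmetric window of half-width `floor(window / 2)` on
#' each side. Near the edges the window shrinks symmetrically so the mean is
#' always centered on the target point (never padded or extrapolated).
#'
#' @param x Numeric vector, ordered.
#' @param window Nominal window width in points (e.g. 50 for a 50-year
#'   moving average of annual values).
#' @return Numeric vector, same length as `x`.
#' @keywords internal
centered_ma <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  k <- pmin(half, seq_len(n) - 1L, n - seq_len(n))
  cs <- cumsum(c(0, x))
  lo <- seq_len(n) - k
  hi <- seq_len(n) + k
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Derive a per-stage seed from the pipeline seed; kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483647L
}
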