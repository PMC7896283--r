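# Attribution of pollen-metric trends to anthropogenic climate change:
# trends predicted under observed vs counterfactual temperatures, the
# percent-contribution statistic, and ensemble aggregation.

#' Trend in a pollen metric predicted from a temperature series
#'
#' Uses a fitted pollen-temperature model to predict the transformed metric
#' for each station and year from the supplied temperature series (fixed
#' effects plus station random effects; stations absent from the fit are
#' predicted from fixed effects alone, with a message), then estimates the
#' cross-station trend of those predictions over the period with the same
#' mixed trend machinery (prediction ~ year, random slope and intercept by
#' station, shared residual variance). When the predictions are exactly
#' linear per station (noise-free temperature ramps) or constant, the mixed
#' fit is degenerate and the trend is taken from a fixed-effects regression
#' with station intercepts instead.
#'
#' @param fit A `pollen_fit` of a metric against a single temperature
#'   predictor (e.g. `mat`).
#' @param temperatures Tibble `station_id`, `year`, and the temperature
#'   column named by `temp_col`.
#' @param period `c(start_year, end_year)`; the series must cover it.
#' @param temp_col Name of the temperature column to predict from.
#' @return One-row tibble: `trend` (per-year slope of the predicted
#'   transformed metric), `std.error`, `method` (`"mixed"` or `"fixed"`),
#'   `n_stations`, `n_years`.
#' @export
predicted_trend <- function(fit, temperatures, period, temp_col = "t_with_acc") {
  stopifnot(inherits(fit, "pollen_fit"), !is.null(fit$model))
  if (length(fit$fixed) != 1) {
    abort("`fit` must have exactly one (temperature) fixed-effect term.")
  }
  stopifnot(all(c("station_id", "year", temp_col) %in% names(temperatures)))
  tt <- temperatures[temperatures$year >= period[1] &
                       temperatures$year <= period[2], ]
  yrs <- sort(unique(tt$year))
  if (length(yrs) < 2 || min(yrs) > period[1] || max(yrs) < period[2]) {
    abort(sprintf(
      "Temperature series does not cover the period %d-%d.",
      period[1], period[2]
    ))
  }

  co <- glmmTMB::fixef(fit$model)$cond
  b0 <- unname(co["(Intercept)"])
  b1 <- unname(co[fit$fixed])
  re <- random_effects(fit)
  slope_col <- fit$random_slope
  idx <- match(tt$station_id, re$station_id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    inform(sprintf(
      "%d station(s) absent from the fit predicted from fixed effects only.",
      dplyr::n_distinct(tt$station_id[unknown])
    ))
  }
  re0 <- ifelse(unknown, 0, re$intercept[idx])
  re1 <- if (!is.null(slope_col) && slope_col %in% names(re)) {
    ifelse(unknown, 0, re[[slope_col]][idx])
  } else {
    0
  }
  tt$.pred <- (b0 + re0) + (b1 + re1) * tt[[temp_col]]

  n_st <- dplyr::n_distinct(tt$station_id)
  if (stats::var(tt$.pred) < 1e-24) {
    return(tibble::tibble(
      trend = 0, std.error = 0, method = "fixed",
      n_stations = n_st, n_years = length(yrs)
    ))
  }

  fixed_trend <- function() {
    m <- if (n_st > 1) {
      stats::lm(.pred ~ year + station_id, data = tt)
    } else {
      stats::lm(.pred ~ year, data = tt)
    }
    # noise-free predictions make lm's own fit diagnostics degenerate
    s <- suppressWarnings(summary(m))$coefficients["year", ]
    tibble::tibble(
      trend = unname(s["Estimate"]), std.error = unname(s["Std. Error"]),
      method = "fixed", n_stations = n_st, n_years = length(yrs)
    )
  }
  # degenerate when predictions are exactly linear per station
  if (n_st < 2) {
    return(fixed_trend())
  }
  per_station_resid <- stats::lm(.pred ~ year * station_id, data = tt)
  if (mean(stats::residuals(per_station_resid)^2) < 1e-18) {
    return(fixed_trend())
  }

  tt$year_c <- tt$year - mean(range(tt$year))
  tr <- tryCatch(
    fit_mixed(tt, ".pred",
      fixed = "year_c", random_slope = "year_c",
      transform = "none", station_variances = FALSE
    ),
    error = function(e) NULL
  )
  if (is.null(tr) || !tr$converged) {
    return(fixed_trend())
  }
  co2 <- tidy(tr)
  tibble::tibble(
    trend = co2$estimate[co2$term == "year_c"],
    std.error = co2$std.error[co2$term == "year_c"],
    method = "mixed",
    n_stations = n_st,
    n_years = length(yrs)
  )
}

#' Percent contribution of anthropogenic climate change to a trend
#'
#' The attribution statistic: `100 * (m_wacc - m_noacc) / m_obs`, where
#' `m_wacc` is the metric trend predicted under observed (with-ACC)
#' temperatures, `m_noacc` the trend predicted under a model's counterfactual
#' no-ACC temperatures, and `m_obs` the observed metric trend. All three must
#' be on the same (transformed) scale. The sign is preserved and values are
#' not clipped: contributions below 0% or above 100% are reported as-is.
#' A zero or missing observed trend yields NA with a message.
#'
#' @param m_wacc,m_noacc,m_obs Numeric vectors (recycled).
#' @return Numeric vector of percent contributions.
#' @export
#' @examples
#' percent_acc_contribution(0.5, 0.2, 1.0) # 30
percent_acc_contribution <- function(m_wacc, m_noacc, m_obs) {
  out <- 100 * (m_wacc - m_noacc) / m_obs
  undef <- is.na(m_obs) | m_obs == 0
  if (any(undef)) {
    inform(sprintf(
      "%d contribution(s) undefined (observed trend zero or missing).",
      sum(undef)
    ))
    out[undef] <- NA_real_
  }
  out
}

#' Ensemble attribution of pollen-metric trends
#'
#' For each metric and period, computes the observed trend (`m_obs`, the
#' fixed-effect year slope from [detect_trend()] on the transformed scale),
#' fits the pollen-temperature sensitivity model (`transform(metric) ~ mat`
#' with random slope/intercept and per-station variances), predicts the
#' trend under observed temperatures (`m_wacc`, shared by all models) and
#' under each model's counterfactual (`m_noacc`), and reports each model's
#' percent ACC contribution. The ensemble distribution is per climate model.
#'
#' @param metrics Metric panel from [pollen_metrics()] (or equivalent).
#' @param climate Station-year covariates with `mat` (see
#'   [annual_covariates()]).
#' @param acc Counterfactual series from [counterfactual()]: `model_id`,
#'   `station_id`, `year`, `t_with_acc`, `t_no_acc`.
#' @param metric_names Metrics to attribute.
#' @param periods List of `c(start_year, end_year)` windows.
#' @param station_variances Passed to the sensitivity and trend fits.
#' @return Tibble of class `pollen_attribution`: one row per
#'   (metric, period, model) with `m_wacc`, `m_noacc`, `m_obs`,
#'   `percent_contribution`. Use [summary.pollen_attribution()] for the
#'   median and interquartile range across models.
#' @export
ensemble_attribution <- function(metrics, climate, acc,
                                 metric_names = c(
                                   "annual_integral", "spring_integral",
                                   "start_doy", "season_length"
                                 ),
                                 periods = list(c(1990, 2018), c(2003, 2018)),
                                 station_variances = TRUE) {
  stopifnot(all(c("model_id", "station_id", "year", "t_with_acc", "t_no_acc")
                %in% names(acc)))
  data <- dplyr::inner_join(
    metrics, climate[, c("station_id", "year", "mat")],
    by = c("station_id", "year")
  )
  data$.mat_c <- data$mat - mean(data$mat, na.rm = TRUE)
  observed_temps <- dplyr::distinct(
    acc, .data$station_id, .data$year, .data$t_with_acc
  )
  models <- sort(unique(acc$model_id))

  rows <- purrr::map(metric_names, function(metric) {
    if (all(is.na(metrics[[metric]]))) {
      inform(sprintf("Metric '%s' is entirely missing; skipped.", metric))
      return(NULL)
    }
    # centered temperature conditions the random-slope fit much better;
    # predicted *trends* are invariant to the centering constant
    sens <- fit_mixed(data, metric,
      fixed = ".mat_c", random_slope = ".mat_c",
      station_variances = station_variances
    )
    purrr::map(periods, function(period) {
      m_obs <- tryCatch(
        tidy(detect_trend(metrics, metric,
          period = period,
          station_variances = station_variances
        ))$slope,
        error = function(e) NA_real_
      )
      m_wacc <- predicted_trend(sens, observed_temps, period,
        temp_col = "t_with_acc"
      )$trend
      purrr::map(models, function(m) {
        m_noacc <- predicted_trend(
          sens, acc[acc$model_id == m, ], period,
          temp_col = "t_no_acc"
        )$trend
        tibble::tibble(
          metric = metric,
          period_start = period[1],
          period_end = period[2],
          model_id = m,
          m_wacc = m_wacc,
          m_noacc = m_noacc,
          m_obs = m_obs
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  if (is.null(rows) || nrow(rows) == 0) abort("No attributable metrics.")
  rows$percent_contribution <- percent_acc_contribution(
    rows$m_wacc, rows$m_noacc, rows$m_obs
  )
  class(rows) <- c("pollen_attribution", class(rows))
  rows
}

#' Summarize an ensemble attribution
#'
#' Median and interquartile range of the percent ACC contribution across
#' climate models, per metric and period.
#'
#' @param object A `pollen_attribution`.
#' @param ... Unused.
#' @return Tibble: `metric`, `period_start`, `period_end`, `n_models`,
#'   `median`, `q25`, `q75`.
#' @export
summary.pollen_attribution <- function(object, ...) {
  object |>
    dplyr::group_by(.data$metric, .data$period_start, .data$period_end) |>
    dplyr::summarise(
      n_models = dplyr::n(),
      median = median(.data$percent_contribution, na.rm = TRUE),
      q25 = quantile(.data$percent_contribution, 0.25, na.rm = TRUE,
                     names = FALSE),
      q75 = quantile(.data$percent_contribution, 0.75, na.rm = TRUE,
                     names = FALSE),
      .groups = "drop"
    )
}
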