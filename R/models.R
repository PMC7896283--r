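# Heteroscedastic random-slope mixed models: trend detection, all-subsets
# AIC driver selection, and marginal/conditional R-squared.

default_transform <- function(response) {
  if (identical(response, "start_doy")) "sqrt" else "log10"
}

apply_transform <- function(x, transform) {
  switch(transform,
    none = x,
    log10 = {
      bad <- !is.na(x) & x <= 0
      if (any(bad)) {
        inform(sprintf(
          "%d non-positive values treated as missing under log10.", sum(bad)
        ))
        x[bad] <- NA_real_
      }
      log10(x)
    },
    sqrt = {
      bad <- !is.na(x) & x < 0
      if (any(bad)) {
        inform(sprintf(
          "%d negative values treated as missing under sqrt.", sum(bad)
        ))
        x[bad] <- NA_real_
      }
      sqrt(x)
    },
    abort(sprintf("Unknown transform '%s'.", transform))
  )
}

back_transform <- function(g, transform) {
  switch(transform, none = g, log10 = 10^g, sqrt = g^2)
}

#' Fit a heteroscedastic random-slope mixed-effects model
#'
#' Fits, by maximum likelihood, the linear mixed model used throughout the
#' pipeline: fixed effects plus a station-level random intercept and random
#' slope (unstructured 2x2 covariance by default), with a separate residual
#' variance for every station (multiplicative factors relative to a reference
#' station). Estimation uses `glmmTMB` with a Gaussian response and
#' `dispformula = ~ station`, which parameterizes exactly this per-station
#' log residual SD. ML (not REML) is used so AIC is comparable across fixed
#' structures.
#'
#' @param data Station-year tibble containing `station_id`, the response and
#'   all fixed terms.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect terms (may be empty for an
#'   intercept-only model).
#' @param random_slope Name of the variable with a station-level random slope,
#'   or NULL for random intercepts only.
#' @param transform `"log10"`, `"sqrt"` or `"none"`, applied to the response
#'   before fitting; `"auto"` (default) uses sqrt for `start_doy` and log10
#'   otherwise. Non-positive values under log10 become missing, never offset.
#' @param station_variances Estimate a separate residual variance per station
#'   (default TRUE); FALSE fits a single shared variance.
#' @param se_fallback Apply the covariance-simplification fallback when
#'   standard errors are undefined (default TRUE). Candidate fits that only
#'   contribute a likelihood (e.g. inside [all_subsets_selection()]) skip it.
#' @param random_cov `"us"` (unstructured intercept-slope covariance, default)
#'   or `"diag"` (independent). When the unstructured fit leaves the
#'   intercept-slope correlation unidentifiable (non-positive-definite
#'   Hessian or undefined standard errors, common when a variance component
#'   is near zero), the model is refit with independent random effects;
#'   `$random_cov_used` records the structure actually fitted.
#' @return Object of class `pollen_fit`: the fitted model plus metadata.
#'   Non-convergence sets `converged = FALSE` rather than erroring.
#'   Methods: [tidy()], [glance()], `print`; see also [r2_nakagawa()],
#'   [station_sigmas()], [random_effects()].
#' @export
#' @examples
#' panel <- withr::with_seed(1, simulate_metric_panel(n_stations = 8))
#' fit <- fit_mixed(panel, "annual_integral",
#'   fixed = "year",
#'   random_slope = "year"
#' )
#' tidy(fit)
#' glance(fit)
fit_mixed <- function(data, response, fixed = character(),
                      random_slope = NULL,
                      transform = c("auto", "log10", "sqrt", "none"),
                      station_variances = TRUE,
                      random_cov = c("us", "diag"),
                      se_fallback = TRUE) {
  transform <- match.arg(transform)
  random_cov <- match.arg(random_cov)
  if (transform == "auto") transform <- default_transform(response)
  stopifnot("station_id" %in% names(data), response %in% names(data))
  missing_terms <- setdiff(c(fixed, random_slope), names(data))
  if (length(missing_terms) > 0) {
    abort(sprintf("Missing columns: %s.", paste(missing_terms, collapse = ", ")))
  }

  df <- tibble::as_tibble(data)
  df$.y <- apply_transform(df[[response]], transform)
  keep <- stats::complete.cases(df[, c(".y", fixed, random_slope)])
  if (any(!keep)) {
    inform(sprintf("%d incomplete rows dropped before fitting.", sum(!keep)))
  }
  df <- df[keep, ]
  df$station_id <- droplevels(factor(df$station_id))
  n_st <- nlevels(df$station_id)
  if (n_st < 2) abort("Need at least 2 stations to fit the mixed model.")
  for (term in fixed) {
    if (sd(df[[term]]) == 0) {
      abort(sprintf("Singular design: predictor '%s' is constant.", term))
    }
  }

  disp <- if (station_variances) ~station_id else ~1
  re_formula <- function(cov_type) {
    if (is.null(random_slope)) {
      "(1 | station_id)"
    } else if (cov_type == "us") {
      sprintf("(1 + %s | station_id)", random_slope)
    } else {
      sprintf("diag(1 + %s | station_id)", random_slope)
    }
  }
  warnings_seen <- character()
  attempt <- function(cov_type) {
    rhs <- paste(c("1", fixed, re_formula(cov_type)), collapse = " + ")
    form <- stats::as.formula(paste(".y ~", rhs))
    withCallingHandlers(
      tryCatch(
        glmmTMB::glmmTMB(form, dispformula = disp, data = df, REML = FALSE),
        error = function(e) e
      ),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  healthy <- function(m) {
    if (inherits(m, "error")) {
      return(FALSE)
    }
    se <- tryCatch(sqrt(diag(stats::vcov(m)$cond)), error = function(e) NaN)
    isTRUE(m$sdr$pdHess) && all(is.finite(se))
  }

  model <- attempt(random_cov)
  cov_used <- random_cov
  # an unidentifiable intercept-slope correlation (boundary fit) leaves the
  # Hessian non-positive-definite; refit with independent random effects.
  # Skipped when only the likelihood is needed (se_fallback = FALSE).
  if (se_fallback && !is.null(random_slope) && random_cov == "us" &&
        !healthy(model)) {
    alt <- attempt("diag")
    if (healthy(alt) ||
          (inherits(model, "error") && !inherits(alt, "error"))) {
      model <- alt
      cov_used <- "diag"
    }
  }
  failed <- inherits(model, "error")
  # the maximized log-likelihood straight from the objective: finite (and the
  # AIC usable) even for boundary fits where glmmTMB::logLik returns NA
  log_lik <- if (failed) NA_real_ else -model$fit$objective
  n_par <- if (failed) NA_integer_ else attr(logLik(model), "df")
  fitted_ok <- !failed && is.finite(log_lik)
  converged <- fitted_ok && isTRUE(model$fit$convergence == 0)

  structure(
    list(
      model = if (failed) NULL else model,
      error = if (failed) conditionMessage(model) else NULL,
      warnings = warnings_seen,
      log_lik = log_lik,
      n_par = n_par,
      aic = -2 * log_lik + 2 * n_par,
      fitted_ok = fitted_ok,
      response = response,
      transform = transform,
      fixed = fixed,
      random_slope = random_slope,
      random_cov = random_cov,
      random_cov_used = cov_used,
      station_variances = station_variances,
      data = df,
      n_obs = nrow(df),
      n_stations = n_st,
      converged = converged,
      pd_hess = if (failed) FALSE else isTRUE(model$sdr$pdHess)
    ),
    class = "pollen_fit"
  )
}

#' @export
print.pollen_fit <- function(x, ...) {
  cat(sprintf(
    "<pollen_fit> %s(%s) ~ %s | random %s by station | %s\n",
    x$transform, x$response,
    if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
    if (is.null(x$random_slope)) "intercept" else paste("1 +", x$random_slope),
    if (x$station_variances) "per-station variances" else "shared variance"
  ))
  if (!is.null(x$error)) {
    cat("  FAILED:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  n = %d obs, %d stations | AIC %.2f | converged: %s\n",
    x$n_obs, x$n_stations, x$aic, x$converged
  ))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_mixed
#' @param x,object A `pollen_fit`.
#' @param ... Unused.
#' @export
tidy.pollen_fit <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(
      term = character(), estimate = double(), std.error = double(),
      statistic = double(), p.value = double()
    ))
  }
  beta <- glmmTMB::fixef(x$model)$cond
  se <- tryCatch(
    sqrt(diag(stats::vcov(x$model)$cond)),
    error = function(e) rep(NA_real_, length(beta))
  )
  z <- beta / se
  tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(z),
    # Wald tests with a normal reference
    p.value = 2 * pnorm(-abs(unname(z)))
  )
}

#' @rdname fit_mixed
#' @export
glance.pollen_fit <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(
      aic = NA_real_, log_lik = NA_real_, df = NA_integer_,
      r2_marginal = NA_real_, r2_conditional = NA_real_,
      n_obs = x$n_obs, n_stations = x$n_stations, converged = FALSE
    ))
  }
  r2 <- tryCatch(r2_nakagawa(x), error = function(e) {
    c(r2_marginal = NA_real_, r2_conditional = NA_real_)
  })
  tibble::tibble(
    aic = x$aic,
    log_lik = x$log_lik,
    df = x$n_par,
    r2_marginal = unname(r2["r2_marginal"]),
    r2_conditional = unname(r2["r2_conditional"]),
    n_obs = x$n_obs,
    n_stations = x$n_stations,
    converged = x$converged
  )
}

#' Per-station residual standard deviations
#'
#' @param fit A `pollen_fit`.
#' @return Tibble `station_id`, `sigma` (residual SD on the model scale).
#' @export
station_sigmas <- function(fit) {
  stopifnot(inherits(fit, "pollen_fit"), !is.null(fit$model))
  stations <- levels(fit$data$station_id)
  if (!fit$station_variances) {
    return(tibble::tibble(
      station_id = stations,
      sigma = glmmTMB::sigma(fit$model)
    ))
  }
  bd <- glmmTMB::fixef(fit$model)$disp
  eta <- bd[1] + c(0, bd[-1])
  tibble::tibble(station_id = stations, sigma = unname(exp(eta)))
}

#' Station-level random effects
#'
#' @param fit A `pollen_fit`.
#' @return Tibble `station_id`, `intercept`, and the random slope when present.
#' @export
random_effects <- function(fit) {
  stopifnot(inherits(fit, "pollen_fit"), !is.null(fit$model))
  re <- glmmTMB::ranef(fit$model)$cond$station_id
  out <- tibble::as_tibble(re, rownames = "station_id")
  names(out)[names(out) == "(Intercept)"] <- "intercept"
  out
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-decomposition R-squared: the marginal R2 is the share of total
#' variance explained by the fixed effects alone,
#' `var_f / (var_f + var_r + var_e)`; the conditional R2 adds the random
#' effects to the numerator. `var_f` is the variance of the fixed-effect
#' predictions, `var_r` the mean (over observations) of `z' G z` with `G` the
#' random-effect covariance and `z` the random-effect design row, and `var_e`
#' the observation-weighted mean of the per-station residual variances.
#'
#' @param fit A converged `pollen_fit`.
#' @return Named numeric vector `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "pollen_fit"))
  if (is.null(fit$model)) abort("Model failed to fit; no R-squared available.")
  df <- fit$data
  beta <- glmmTMB::fixef(fit$model)$cond
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", fit$fixed), collapse = " + "))),
    df
  )
  var_f <- if (length(fit$fixed) == 0) 0 else var(as.vector(X %*% beta))

  G <- glmmTMB::VarCorr(fit$model)$cond$station_id
  G <- matrix(as.numeric(G), nrow = nrow(G))
  Z <- if (is.null(fit$random_slope)) {
    matrix(1, nrow(df), 1)
  } else {
    cbind(1, df[[fit$random_slope]])
  }
  var_r <- mean(rowSums((Z %*% G) * Z))

  sig <- station_sigmas(fit)
  var_e <- mean(sig$sigma[match(df$station_id, sig$station_id)]^2)

  total <- var_f + var_r + var_e
  if (total <= 0) abort("Zero total variance; R-squared undefined.")
  c(
    r2_marginal = var_f / total,
    r2_conditional = (var_f + var_r) / total
  )
}

#' Detect a long-term trend in a pollen metric
#'
#' Fits `transform(metric) ~ year` with the standard random slope/intercept
#' and per-station variance structure, and summarizes the fixed-effect trend
#' as a change over the record: for log10 metrics the percent change over the
#' span is `100 * (10^(slope * span) - 1)`; for sqrt metrics (season start
#' date) the change in days is obtained from the fixed-effect predictions at
#' the endpoints. Confidence limits propagate the slope's Wald 95% CI.
#'
#' @param data Metric panel: tibble with `station_id`, `year`, and the metric.
#' @param metric Metric column name.
#' @param period Optional `c(start_year, end_year)` restriction.
#' @param transform,station_variances Passed to [fit_mixed()].
#' @return Object of class `pollen_trend`: list with the `pollen_fit` and a
#'   one-row `summary` tibble (slope on the transformed scale, its SE and
#'   p-value, span, back-transformed `change` and `percent_change` with 95%
#'   CI). `tidy()` returns the summary row.
#' @export
#' @examples
#' panel <- withr::with_seed(1, simulate_metric_panel(n_stations = 10))
#' tr <- detect_trend(panel, "annual_integral")
#' tidy(tr)
detect_trend <- function(data, metric, period = NULL,
                         transform = "auto", station_variances = TRUE) {
  stopifnot("year" %in% names(data))
  df <- tibble::as_tibble(data)
  if (!is.null(period)) {
    df <- df[df$year >= period[1] & df$year <= period[2], ]
  }
  ok <- !is.na(df[[metric]])
  if (dplyr::n_distinct(df$station_id[ok]) < 2) {
    abort(sprintf("Metric '%s' present for fewer than 2 stations.", metric))
  }
  center <- mean(range(df$year))
  df$year_c <- df$year - center # centering affects the intercept only
  fit <- fit_mixed(df, metric,
    fixed = "year_c", random_slope = "year_c",
    transform = transform, station_variances = station_variances
  )
  co <- tidy(fit)
  b0 <- co$estimate[co$term == "(Intercept)"]
  b1 <- co$estimate[co$term == "year_c"]
  se <- co$std.error[co$term == "year_c"]
  p <- co$p.value[co$term == "year_c"]
  y0 <- min(fit$data$year)
  y1 <- max(fit$data$year)
  span <- y1 - y0

  change_from <- function(slope) {
    g0 <- b0 + slope * (y0 - center)
    g1 <- b0 + slope * (y1 - center)
    v0 <- back_transform(g0, fit$transform)
    v1 <- back_transform(g1, fit$transform)
    c(change = v1 - v0, percent = 100 * (v1 / v0 - 1))
  }
  est <- change_from(b1)
  lo <- change_from(b1 - qnorm(0.975) * se)
  hi <- change_from(b1 + qnorm(0.975) * se)
  # for decreasing metrics the "lo" slope can give the larger change
  ci_change <- range(lo["change"], hi["change"])
  ci_pct <- range(lo["percent"], hi["percent"])

  summary <- tibble::tibble(
    metric = metric,
    transform = fit$transform,
    n_obs = fit$n_obs,
    n_stations = fit$n_stations,
    year_start = y0,
    year_end = y1,
    slope = b1,
    std.error = se,
    p.value = p,
    change = unname(est["change"]),
    change_low = ci_change[1],
    change_high = ci_change[2],
    percent_change = unname(est["percent"]),
    percent_low = ci_pct[1],
    percent_high = ci_pct[2],
    converged = fit$converged
  )
  structure(list(fit = fit, summary = summary), class = "pollen_trend")
}

#' @export
print.pollen_trend <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pollen_trend> %s, %d-%d (%d obs, %d stations)\n",
    s$metric, s$year_start, s$year_end, s$n_obs, s$n_stations
  ))
  cat(sprintf(
    "  slope (%s scale) %.5f +/- %.5f per yr, p = %.3g\n",
    s$transform, s$slope, s$std.error, s$p.value
  ))
  cat(sprintf(
    "  change over record: %.3g [%.3g, %.3g] (%.1f%% [%.1f%%, %.1f%%])\n",
    s$change, s$change_low, s$change_high,
    s$percent_change, s$percent_low, s$percent_high
  ))
  invisible(x)
}

#' @rdname detect_trend
#' @param x A `pollen_trend`.
#' @param ... Unused.
#' @export
tidy.pollen_trend <- function(x, ...) x$summary

#' @rdname detect_trend
#' @export
glance.pollen_trend <- function(x, ...) glance(x$fit)

#' All-subsets AIC selection of climate drivers
#'
#' Fits every subset of the candidate predictors (main effects only,
#' including the intercept-only model) as fixed effects in the standard
#' mixed model, ranks them by AIC, and reports delta-AIC and marginal/
#' conditional R2 for each. Models within `aic_window` (default 3) of the
#' best AIC form the plausible set; within it, the model maximizing the
#' marginal R2 is marked `selected`. Predictors are z-scored before fitting
#' for conditioning; the selected model is refit on the natural scale and
#' attached as attribute `"best_fit"`.
#'
#' @param data Station-year tibble with `station_id`, the response and all
#'   candidate predictors.
#' @param response Response column name.
#' @param predictors Character vector of candidate predictor columns.
#' @param random_slope Variable given a station-level random slope in every
#'   candidate (default `"mat"` when present, else the first predictor),
#'   keeping the random structure fixed across the candidate set.
#' @param transform,station_variances Passed to [fit_mixed()].
#' @param aic_window Delta-AIC defining the plausible set (default 3).
#' @return Tibble of class `pollen_selection`, one row per candidate, ranked:
#'   `rank`, `terms`, `n_terms`, `df`, `log_lik`, `aic`, `delta_aic`,
#'   `r2_marginal`, `r2_conditional`, `converged`, `in_top_set`, `selected`.
#'   Ties in AIC break toward fewer parameters, then higher marginal R2.
#'   Candidates that fail to yield a maximized likelihood are retained,
#'   flagged, and ranked last; boundary fits (variance components at zero)
#'   keep their AIC with `converged = FALSE`.
#' @export
all_subsets_selection <- function(data, response, predictors,
                                  random_slope = NULL,
                                  transform = "auto",
                                  station_variances = TRUE,
                                  aic_window = 3) {
  stopifnot(length(predictors) >= 1)
  if (is.null(random_slope)) {
    random_slope <- if ("mat" %in% predictors) "mat" else predictors[1]
  }
  df <- tibble::as_tibble(data)
  keep <- stats::complete.cases(df[, c(response, predictors)])
  df <- df[keep, ]
  scaling <- tibble::tibble(
    term = predictors,
    mean = vapply(predictors, function(p) mean(df[[p]]), 0),
    sd = vapply(predictors, function(p) sd(df[[p]]), 0)
  )
  if (any(scaling$sd == 0)) {
    constant <- scaling$term[scaling$sd == 0]
    warn(sprintf(
      "Constant predictor(s) excluded from the candidate set: %s.",
      paste(constant, collapse = ", ")
    ))
    predictors <- setdiff(predictors, constant)
    if (length(predictors) == 0) abort("All candidate predictors are constant.")
    scaling <- scaling[scaling$sd > 0, ]
  }
  scaled <- df
  for (p in predictors) {
    scaled[[p]] <- (df[[p]] - scaling$mean[scaling$term == p]) /
      scaling$sd[scaling$term == p]
  }

  subsets <- unlist(
    lapply(0:length(predictors), function(k) {
      combn(predictors, k, simplify = FALSE)
    }),
    recursive = FALSE
  )
  rows <- purrr::map(subsets, function(terms) {
    fit <- tryCatch(
      fit_mixed(scaled, response,
        fixed = terms, random_slope = random_slope,
        transform = transform, station_variances = station_variances,
        se_fallback = FALSE
      ),
      error = function(e) NULL
    )
    g <- if (is.null(fit)) {
      tibble::tibble(
        aic = NA_real_, log_lik = NA_real_, df = NA_integer_,
        r2_marginal = NA_real_, r2_conditional = NA_real_, converged = FALSE
      )
    } else {
      glance(fit)
    }
    tibble::tibble(
      terms = if (length(terms)) paste(terms, collapse = " + ") else "1",
      n_terms = length(terms),
      df = g$df,
      log_lik = g$log_lik,
      aic = g$aic, # finite whenever a maximized likelihood was found
      r2_marginal = g$r2_marginal,
      r2_conditional = g$r2_conditional,
      converged = isTRUE(g$converged)
    )
  })
  tab <- purrr::list_rbind(rows)

  usable <- is.finite(tab$aic)
  if (!any(usable)) abort("No candidate model could be fit.")
  best_aic <- min(tab$aic[usable])
  tab$delta_aic <- tab$aic - best_aic
  ord <- order(
    !usable, # models without a likelihood rank last
    tab$aic, tab$n_terms, -tab$r2_marginal,
    method = "radix", na.last = TRUE
  )
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  tab$in_top_set <- !is.na(tab$delta_aic) & tab$delta_aic <= aic_window
  tab$selected <- FALSE
  if (any(tab$in_top_set)) {
    top <- which(tab$in_top_set)
    tab$selected[top[which.max(tab$r2_marginal[top])]] <- TRUE
  }
  tab <- tab[, c(
    "rank", "terms", "n_terms", "df", "log_lik", "aic", "delta_aic",
    "r2_marginal", "r2_conditional", "converged", "in_top_set", "selected"
  )]

  sel_terms <- tab$terms[tab$selected]
  best_fit <- NULL
  if (length(sel_terms) == 1) {
    terms <- if (sel_terms == "1") character() else strsplit(sel_terms, " \\+ ")[[1]]
    best_fit <- tryCatch(
      fit_mixed(df, response,
        fixed = terms, random_slope = random_slope,
        transform = transform, station_variances = station_variances
      ),
      error = function(e) NULL
    )
  }
  attr(tab, "best_fit") <- best_fit
  attr(tab, "scaling") <- scaling
  attr(tab, "response") <- response
  class(tab) <- c("pollen_selection", class(tab))
  tab
}
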