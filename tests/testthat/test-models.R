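# Mixed-model machinery: likelihood correctness, coverage, parameter
# recovery, R2 decomposition, trend summaries, and all-subsets selection.

test_that("maximized likelihood matches a hand-computed Gaussian marginal", {
  # 4-station toy; the oracle evaluates the marginal likelihood by plain
  # matrix algebra at the fitted parameters
  df <- withr::with_seed(101, {
    st <- rep(sprintf("S%d", 1:4), each = 12)
    x <- rep(seq(-2, 2, length.out = 12), 4)
    b0 <- rnorm(4, 0, 0.8)[factor(st)]
    b1 <- rnorm(4, 0.5, 0.3)[factor(st)]
    tibble::tibble(
      station_id = st, x = x,
      y = b0 + b1 * x + rnorm(48, 0, 0.4)
    )
  })
  fit <- fit_mixed(df, "y",
    fixed = "x", random_slope = "x",
    transform = "none", station_variances = FALSE
  )
  G <- glmmTMB::VarCorr(fit$model)$cond$station_id
  G <- matrix(as.numeric(G), 2)
  sig <- station_sigmas(fit)
  sigmas <- setNames(as.list(sig$sigma), sig$station_id)
  ll <- oracle_marginal_loglik(
    df, "y", "x", "x",
    beta = glmmTMB::fixef(fit$model)$cond, G = G, sigmas = sigmas
  )
  expect_equal(fit$log_lik, ll, tolerance = 1e-4)

  # heteroscedastic variant
  fit2 <- fit_mixed(df, "y",
    fixed = "x", random_slope = "x",
    transform = "none", station_variances = TRUE
  )
  sig2 <- station_sigmas(fit2)
  ll2 <- oracle_marginal_loglik(
    df, "y", "x", "x",
    beta = glmmTMB::fixef(fit2$model)$cond,
    G = matrix(as.numeric(glmmTMB::VarCorr(fit2$model)$cond$station_id), 2),
    sigmas = setNames(as.list(sig2$sigma), sig2$station_id)
  )
  expect_equal(fit2$log_lik, ll2, tolerance = 1e-4)
  # and the AIC identity on the stored quantities
  expect_equal(fit2$aic, -2 * fit2$log_lik + 2 * fit2$n_par)
})

test_that("the fitted model agrees with nlme::lme on the same data", {
  skip_if_not_installed("nlme")
  panel <- withr::with_seed(103, simulate_metric_panel(
    n_stations = 10, years = 2000:2014
  ))
  panel$year_c <- panel$year - 2007
  fit <- fit_mixed(panel, "annual_integral",
    fixed = "year_c",
    random_slope = "year_c"
  )
  ref <- nlme::lme(
    log10(annual_integral) ~ year_c,
    random = ~year_c | station_id,
    weights = nlme::varIdent(form = ~1 | station_id),
    data = panel, method = "ML",
    control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                               returnObject = TRUE)
  )
  expect_equal(fit$log_lik, as.numeric(logLik(ref)), tolerance = 1e-3)
  expect_equal(
    tidy(fit)$estimate,
    unname(nlme::fixef(ref)),
    tolerance = 1e-4
  )
})

test_that("confidence intervals cover a null year effect at the stated rate", {
  # Wald intervals with a normal reference undercover slightly at 6 stations
  # (t with ~5 df); nominal-rate coverage at study scale is exercised in the
  # acceptance suite. Here the check is calibration, not nominal exactness.
  covered <- withr::with_seed(107, vapply(1:200, function(i) {
    panel <- simulate_metric_panel(
      n_stations = 6, years = 2001:2012,
      slope = 0, slope_sd = 0.004,
      sigma_range = c(0.05, 0.2)
    )
    panel$year_c <- panel$year - 2006
    fit <- fit_mixed(panel, "annual_integral",
      fixed = "year_c",
      random_slope = "year_c"
    )
    co <- tidy(fit)
    b <- co$estimate[2]
    se <- co$std.error[2]
    is.finite(se) && abs(b) <= qnorm(0.975) * se
  }, NA))
  expect_gt(mean(covered), 0.82)
  expect_lte(mean(covered), 0.99)
})

test_that("planted temperature sensitivity is recovered within 3 SE", {
  truth <- truth_params(n_stations = 25, years = 1990:2018, seed = 109)
  bundle <- simulate_pollen_study(truth, n_models = 1)
  m <- pollen_metrics(bundle$records)
  cov <- annual_covariates(
    extract_station_series(bundle$observed_climate, bundle$stations)
  )
  d <- dplyr::inner_join(m, cov[, c("station_id", "year", "mat")],
    by = c("station_id", "year")
  )
  d$mat_c <- d$mat - mean(d$mat)
  fit <- fit_mixed(d, "annual_integral", fixed = "mat_c", random_slope = "mat_c")
  co <- tidy(fit)
  expect_lt(
    abs(co$estimate[2] - truth$beta_t),
    3 * co$std.error[2]
  )
})

test_that("singular designs and log10 zeros are handled as documented", {
  panel <- withr::with_seed(113, simulate_metric_panel(n_stations = 4))
  panel$const <- 1
  expect_error(
    fit_mixed(panel, "annual_integral", fixed = "const"),
    "const"
  )
  panel$annual_integral[1:3] <- 0
  expect_message(
    fit_mixed(panel, "annual_integral", fixed = "year", random_slope = "year"),
    "non-positive"
  )
})

test_that("variance decomposition R2 behaves at its extremes", {
  # response = pure station intercepts: marginal ~ 0, conditional near 1
  withr::with_seed(127, {
    st <- rep(sprintf("S%d", 1:12), each = 20)
    y <- rnorm(12, 0, 2)[factor(st)] + rnorm(240, 0, 0.1)
    x <- rnorm(240)
    df <- tibble::tibble(station_id = st, y = y, x = x)
    fit <- fit_mixed(df, "y", fixed = "x", transform = "none",
                     station_variances = FALSE)
    r2 <- r2_nakagawa(fit)
    expect_lt(r2["r2_marginal"], 0.05)
    expect_gt(r2["r2_conditional"], 0.95)
    expect_lte(r2["r2_marginal"], r2["r2_conditional"])
  })

  # negligible random effects: both R2 collapse to the classical R2
  withr::with_seed(131, {
    st <- rep(sprintf("S%d", 1:10), each = 30)
    x <- rnorm(300)
    y <- 1 + 0.8 * x + rnorm(300, 0, 0.5)
    df <- tibble::tibble(station_id = st, y = y, x = x)
    fit <- fit_mixed(df, "y", fixed = "x", transform = "none",
                     station_variances = FALSE)
    r2 <- r2_nakagawa(fit)
    r2_ols <- summary(lm(y ~ x, df))$r.squared
    expect_equal(unname(r2["r2_marginal"]), r2_ols, tolerance = 0.02)
    expect_equal(unname(r2["r2_conditional"]), r2_ols, tolerance = 0.02)
  })
})

test_that("R2 matches the closed-form decomposition with known components", {
  withr::with_seed(137, {
    n_st <- 40
    n_yr <- 25
    tau0 <- 0.5
    sigma <- 0.3
    beta <- 0.7
    st <- rep(sprintf("S%02d", 1:n_st), each = n_yr)
    x <- rnorm(n_st * n_yr)
    y <- rnorm(n_st, 0, tau0)[factor(st)] + beta * x +
      rnorm(n_st * n_yr, 0, sigma)
    df <- tibble::tibble(station_id = st, y = y, x = x)
    fit <- fit_mixed(df, "y", fixed = "x", transform = "none",
                     station_variances = FALSE)
    r2 <- r2_nakagawa(fit)
    expected <- oracle_r2(beta^2 * var(x), tau0^2, sigma^2)
    expect_equal(unname(r2["r2_marginal"]), unname(expected["r2_marginal"]),
      tolerance = 0.05
    )
    expect_equal(unname(r2["r2_conditional"]),
      unname(expected["r2_conditional"]),
      tolerance = 0.05
    )
  })
})

test_that("detect_trend back-transforms slopes as documented", {
  # near-noiseless planted log10 slope: percent change follows
  # 100 * (10^(slope * span) - 1)
  panel <- withr::with_seed(139, simulate_metric_panel(
    n_stations = 5, years = 1990:2018,
    slope = 0.00285, slope_sd = 1e-10, sigma_range = c(1e-6, 2e-6)
  ))
  tr <- tidy(detect_trend(panel, "annual_integral"))
  expect_equal(tr$slope, 0.00285, tolerance = 1e-3)
  expect_equal(tr$percent_change, 100 * (10^(0.00285 * 28) - 1),
    tolerance = 0.1
  )

  # null slope: the percent-change CI covers zero
  panel0 <- withr::with_seed(149, simulate_metric_panel(
    n_stations = 10, years = 1990:2018, slope = 0
  ))
  tr0 <- tidy(detect_trend(panel0, "annual_integral"))
  expect_lt(tr0$percent_low, 0)
  expect_gt(tr0$percent_high, 0)

  # sqrt metric: a planted ~20-day start advance is recovered within the CI
  panel_s <- withr::with_seed(151, simulate_metric_panel(
    n_stations = 20, years = 1990:2018,
    slope = -0.0125, slope_sd = 0.002, # sqrt scale: ~ -20 d over 28 y
    intercept_mean = sqrt(105), intercept_sd = 0.3,
    sigma_range = c(0.1, 0.3), transform = "sqrt", metric = "start_doy"
  ))
  tr_s <- tidy(detect_trend(panel_s, "start_doy"))
  expect_equal(tr_s$transform, "sqrt")
  planted_change <- (sqrt(105) - 0.0125 * 28)^2 - 105
  expect_gt(planted_change, tr_s$change_low)
  expect_lt(planted_change, tr_s$change_high)
  expect_lt(tr_s$change, 0)
})

test_that("detect_trend is equivariant to year recentering", {
  panel <- withr::with_seed(157, simulate_metric_panel(n_stations = 6))
  t1 <- tidy(detect_trend(panel, "annual_integral"))
  shifted <- panel
  shifted$year <- shifted$year + 1000
  t2 <- tidy(detect_trend(shifted, "annual_integral"))
  expect_equal(t1$slope, t2$slope, tolerance = 1e-5)
  expect_equal(t1$percent_change, t2$percent_change, tolerance = 1e-3)
})

test_that("all-subsets table enumerates, ranks and flags candidates", {
  withr::with_seed(163, {
    panel <- simulate_metric_panel(n_stations = 8, years = 2001:2015)
    panel$mat <- rnorm(nrow(panel), 15, 2)
    panel$map <- runif(nrow(panel), 500, 1200)
    # response driven by mat only, on top of the panel's station structure
    panel$annual_integral <- panel$annual_integral *
      10^(0.1 * (panel$mat - 15))
    sel <- all_subsets_selection(panel, "annual_integral",
      predictors = c("mat", "map")
    )
    expect_equal(nrow(sel), 4)
    expect_setequal(sel$terms, c("1", "mat", "map", "mat + map"))
    expect_equal(sel$rank, 1:4)
    expect_equal(sel$delta_aic[1], 0)
    expect_true(grepl("mat", sel$terms[sel$selected]))
    expect_true(all(sel$r2_marginal <= sel$r2_conditional + 1e-9, na.rm = TRUE))
    # the winning model's AIC beats the intercept-only model decisively
    expect_gt(sel$delta_aic[sel$terms == "1"], 3)

    bf <- attr(sel, "best_fit")
    expect_s3_class(bf, "pollen_fit")
    # natural-scale refit: slope per degree recovered
    co <- tidy(bf)
    expect_equal(co$estimate[co$term == "mat"], 0.1, tolerance = 0.02)
  })
})

test_that("adding a pure-noise predictor rarely lowers AIC", {
  # a fixed common random-effect structure keeps the candidate models nested
  res <- withr::with_seed(167, purrr::map(1:40, function(i) {
    panel <- simulate_metric_panel(
      n_stations = 10, years = 2001:2015,
      slope_sd = 0.003
    )
    panel$year_c <- panel$year - 2008
    panel$noise <- rnorm(nrow(panel))
    base <- fit_mixed(panel, "annual_integral",
      fixed = "year_c",
      random_slope = "year_c", random_cov = "diag"
    )
    plus <- fit_mixed(panel, "annual_integral",
      fixed = c("year_c", "noise"),
      random_slope = "year_c", random_cov = "diag"
    )
    c(
      dll = plus$log_lik - base$log_lik,
      daic = plus$aic - base$aic
    )
  }))
  dll <- vapply(res, `[[`, 0, "dll")
  daic <- vapply(res, `[[`, 0, "daic")
  # a nested model never has higher likelihood (tiny numeric slack)
  expect_true(all(dll > -1e-3))
  expect_gt(mean(daic > 0), 0.75)
})
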