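# Pollen metrics: inclusion rules, interpolation, season bounds, integrals,
# statistics, and the sampling-bias diagnostics.

test_that("inclusion rules drop short stations and sparse years", {
  # station A: 4 dense years -> dropped by the min-years rule
  # station B: 6 dense years + one 9-measurement year -> year dropped only
  a <- make_box_station("A", 2001:2004)
  b <- make_box_station("B", 2001:2006)
  b_sparse <- make_records(seq(10, 90, by = 10), rep(5, 9),
    year = 2007, station = "B"
  )
  out <- qc_filter(dplyr::bind_rows(a, b, b_sparse))
  expect_false("A" %in% out$records$station_id)
  expect_true("B" %in% out$records$station_id)
  yrs_b <- unique(format(out$records$date[out$records$station_id == "B"], "%Y"))
  expect_false("2007" %in% yrs_b)
  expect_true(any(out$exclusions$station_id == "A" &
    is.na(out$exclusions$year)))
  expect_true(any(out$exclusions$station_id == "B" &
    out$exclusions$year == 2007))

  # a station kept only if >= 5 years survive the measurement rule
  c_ok <- make_box_station("C", 2001:2005)
  c_sparse <- make_records(1:9, rep(1, 9), year = 2006, station = "C")
  out2 <- qc_filter(dplyr::bind_rows(c_ok, c_sparse))
  expect_true("C" %in% out2$records$station_id)

  expect_error(qc_filter(make_records(integer(), numeric())), "no records")
})

test_that("dense synthetic networks pass QC with zero exclusions", {
  recs <- purrr::map(
    c("A", "B", "C"),
    ~ make_box_station(.x, 2001:2008)
  ) |> purrr::list_rbind()
  out <- qc_filter(recs)
  expect_equal(nrow(out$exclusions), 0)
  expect_equal(nrow(out$records), nrow(recs))
})

test_that("duplicate (station, date) records are averaged with a warning", {
  rec <- make_records(c(10, 10, 12), c(100, 200, 300))
  expect_warning(out <- pollenattrib:::dedupe_records(rec), "duplicate")
  expect_equal(nrow(out), 2)
  expect_equal(out$concentration[1], 150)
})

test_that("interpolation is linear, exact at knots, never extrapolates", {
  rec <- make_records(c(10, 12), c(100, 200))
  daily <- interpolate_daily(rec)
  expect_equal(daily$doy, 10:12)
  expect_equal(daily$concentration, c(100, 150, 200))

  # identity on dense input
  dense <- make_records(1:50, runif(50))
  expect_equal(interpolate_daily(dense)$concentration, dense$concentration)

  # exact reconstruction of a piecewise-linear curve sampled at random knots
  withr::with_seed(9, {
    knots <- sort(sample(1:200, 12))
    vals <- cumsum(runif(12, -5, 5)) + 10
    full <- approx(knots, vals, xout = knots[1]:knots[12])$y
    sub <- make_records(knots, vals)
    expect_equal(interpolate_daily(sub)$concentration, full)
  })

  expect_error(interpolate_daily(make_records(5, 1)), "fewer than 2")
  expect_error(
    interpolate_daily(dplyr::bind_rows(
      make_records(5, 1, year = 2001), make_records(5, 1, year = 2002)
    )),
    "single calendar year"
  )
})

test_that("interpolated values stay within bracketing measurements", {
  withr::with_seed(10, {
    for (i in 1:20) {
      doy <- sort(sample(1:300, 8))
      conc <- runif(8, 0, 100)
      daily <- interpolate_daily(make_records(doy, conc))
      for (j in seq_len(7)) {
        seg <- daily$concentration[daily$doy >= doy[j] & daily$doy <= doy[j + 1]]
        expect_true(all(seg >= min(conc[j:(j + 1)]) - 1e-12))
        expect_true(all(seg <= max(conc[j:(j + 1)]) + 1e-12))
      }
    }
  })
})

test_that("season bounds find the box signal and handle degenerate years", {
  conc <- rep(0, 365)
  conc[100:200] <- 7
  daily <- tibble::tibble(doy = 1:365, concentration = conc)
  b <- season_bounds(daily, threshold = 1)
  expect_equal(b$start_doy, 100)
  expect_equal(b$end_doy, 200)
  expect_equal(b$season_length, 101)

  none <- season_bounds(daily, threshold = 10)
  expect_true(is.na(none$start_doy))
  expect_true(is.na(none$season_length))

  zero <- season_bounds(
    tibble::tibble(doy = 1:365, concentration = rep(0, 365)),
    threshold = 0
  )
  expect_true(is.na(zero$start_doy))
})

test_that("season bounds shift monotonically in the threshold percentile", {
  truth <- truth_params(n_stations = 1, years = 2001:2006, seed = 15)
  bundle <- simulate_pollen_study(truth, n_models = 1)
  recs <- bundle$records
  pcts <- seq(20, 40, by = 5)
  bounds <- purrr::map(pcts, function(p) {
    m <- pollen_metrics(recs, percentile = p, qc = FALSE)
    c(start = mean(m$start_doy), end = mean(m$end_doy))
  })
  starts <- vapply(bounds, `[[`, 0, "start")
  ends <- vapply(bounds, `[[`, 0, "end")
  expect_true(all(diff(starts) >= 0)) # start nondecreasing in percentile
  expect_true(all(diff(ends) <= 0)) # end nonincreasing
})

test_that("seasonal integrals do calendar arithmetic, leap-aware", {
  flat <- tibble::tibble(
    doy = 1:365, date = as.Date("2001-01-01") + 0:364,
    concentration = 1
  )
  v <- seasonal_integrals(flat)
  expect_equal(v$annual_integral, 365)
  expect_equal(v$spring_integral, 120) # Feb 1 - May 31
  expect_equal(v$summer_integral, 92) # Jun 1 - Aug 31
  expect_equal(v$fall_integral, 91) # Sep 1 - Nov 30

  leap <- tibble::tibble(doy = 1:366, concentration = 1)
  vl <- seasonal_integrals(leap, year = 2004)
  expect_equal(vl$annual_integral, 366)
  expect_equal(vl$spring_integral, 121)

  # brute-force window sum on a synthetic two-lobe curve
  truth <- truth_params(n_stations = 1, years = 2001:2006, seed = 2)
  curve <- withr::with_seed(1, generate_daily_emission_curve(
    truth, "S001", truth$stations$ref_temp[1], 2001
  ))
  v2 <- seasonal_integrals(curve, year = 2001)
  expect_equal(v2$spring_integral, sum(curve$concentration[32:151]))
  expect_equal(v2$fall_integral, sum(curve$concentration[244:334]))
})

test_that("integrals are additive over adjacent windows", {
  withr::with_seed(3, {
    conc <- runif(365)
    daily <- tibble::tibble(doy = 1:365, concentration = conc)
    a <- sum(daily$concentration[daily$doy >= 1 & daily$doy <= 100])
    b <- sum(daily$concentration[daily$doy >= 101 & daily$doy <= 365])
    expect_equal(a + b, sum(conc))
  })
})

test_that("daily statistics agree with sort-based oracles", {
  s <- daily_stats(tibble::tibble(concentration = c(1, 2, 3)))
  expect_equal(unlist(s), c(max_daily = 3, mean_daily = 2, median_daily = 2))

  const <- daily_stats(tibble::tibble(concentration = rep(4.2, 10)))
  expect_equal(const$max_daily, const$mean_daily)
  expect_equal(const$mean_daily, const$median_daily)

  withr::with_seed(4, {
    x <- runif(101)
    s2 <- daily_stats(tibble::tibble(concentration = x))
    xs <- sort(x)
    expect_equal(s2$max_daily, xs[101])
    expect_equal(s2$median_daily, xs[51])
    expect_equal(s2$mean_daily, sum(x) / 101)
  })
})

test_that("missed-start flag compares the first measurement to the threshold", {
  expect_false(flag_missed_start(make_records(c(1, 50), c(0, 10)), threshold = 2))
  expect_true(flag_missed_start(make_records(c(1, 50), c(5, 10)), threshold = 2))
  # dense sampling from Jan 1 of a spring-peaked curve starts below threshold
  truth <- truth_params(n_stations = 1, years = 2001:2006, seed = 2)
  curve <- withr::with_seed(2, generate_daily_emission_curve(
    truth, "S001", truth$stations$ref_temp[1], 2001
  ))
  rec <- make_records(curve$doy, curve$concentration)
  thr <- quantile(curve$concentration, 0.3, names = FALSE)
  expect_false(flag_missed_start(rec, thr))
})

test_that("station thresholds use type-7 percentiles, pooled or by year", {
  rec <- dplyr::bind_rows(
    make_records(1:10, 1:10, year = 2001),
    make_records(1:10, 11:20, year = 2002)
  )
  thr <- station_thresholds(rec, percentile = 30)
  expect_equal(thr$threshold, quantile(1:20, 0.3, type = 7, names = FALSE))
  thr_y <- station_thresholds(rec, percentile = 30, pooled = FALSE)
  expect_equal(nrow(thr_y), 2)
  expect_equal(
    thr_y$threshold[thr_y$year == 2001],
    quantile(1:10, 0.3, type = 7, names = FALSE)
  )
})

test_that("metrics pipeline is deterministic and insensitive to redundant points", {
  truth <- truth_params(n_stations = 2, years = 2001:2006, seed = 8)
  bundle <- simulate_pollen_study(truth, n_models = 1)
  m1 <- pollen_metrics(bundle$records)
  m2 <- pollen_metrics(bundle$records)
  expect_identical(m1, m2)

  # adding a measurement that equals the interpolated value changes nothing
  rec <- make_records(c(10, 14), c(100, 200))
  base_daily <- interpolate_daily(rec)
  rec2 <- dplyr::bind_rows(rec, make_records(12, 150))
  expect_equal(interpolate_daily(rec2)$concentration, base_daily$concentration)
  b1 <- season_bounds(base_daily, 120)
  b2 <- season_bounds(interpolate_daily(rec2), 120)
  expect_identical(b1, b2)
})

test_that("pollen_metrics returns one row per retained station-year", {
  truth <- truth_params(n_stations = 3, years = 2001:2007, seed = 12)
  bundle <- simulate_pollen_study(truth, n_models = 1)
  m <- pollen_metrics(bundle$records)
  expect_equal(nrow(m), 3 * 7)
  expect_true(all(m$season_length == m$end_doy - m$start_doy + 1, na.rm = TRUE))
  expect_true(all(m$annual_integral >= m$spring_integral, na.rm = TRUE))
  expect_true(all(m$annual_integral >= m$fall_integral, na.rm = TRUE))
  expect_true(all(m$n_measurements >= 10))
  expect_s3_class(attr(m, "exclusions"), "tbl_df")
})

test_that("sampling-bias test holds its level under the null", {
  gen_station <- function(st, n_years, shift = 1) {
    purrr::map(seq_len(n_years), function(i) {
      first <- rlnorm(5, log(10), 0.5) * (if (i > n_years / 2) shift else 1)
      make_records(c(5, 8, 11, 14, 17), first,
        year = 2000 + i, station = st
      )
    }) |> purrr::list_rbind()
  }
  pooled_p <- withr::with_seed(31, vapply(1:200, function(i) {
    recs <- dplyr::bind_rows(gen_station("A", 20), gen_station("B", 20))
    sampling_bias_test(recs)$pooled$p_value[1]
  }, 0))
  rate <- mean(pooled_p < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)

  # power: a 10x shift in the second half is detected at 20 years
  shifted <- withr::with_seed(32, gen_station("A", 20, shift = 10))
  res <- sampling_bias_test(shifted)
  expect_lt(res$by_station$p_value[1], 0.01)

  # minimal size runs without error
  small <- withr::with_seed(33, gen_station("A", 6))
  expect_no_error(sampling_bias_test(small))
})
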