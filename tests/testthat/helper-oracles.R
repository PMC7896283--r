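# Independent oracles and small fixture builders shared across tests.

# Records tibble from day-of-year / concentration vectors.
make_records <- function(doy, conc, year = 2001, station = "A") {
  tibble::tibble(
    station_id = station,
    date = as.Date(paste0(year, "-01-01")) + doy - 1,
    concentration = conc
  )
}

# Dense multi-year records for one station: constant box signal each year.
make_box_station <- function(station, years, peak = 100, lo = 100, hi = 200) {
  purrr::map(years, function(y) {
    n <- if ((y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0) 366 else 365
    conc <- rep(0, n)
    conc[lo:hi] <- peak
    make_records(seq_len(n), conc, year = y, station = station)
  }) |> purrr::list_rbind()
}

# Brute-force marginal log-likelihood of the heteroscedastic random-slope
# mixed model: y_s ~ N(X_s beta, Z_s G Z_s' + sigma_s^2 I), summed over
# stations. Plain matrix algebra, independent of any fitting backend.
oracle_marginal_loglik <- function(df, response, fixed, random_slope,
                                   beta, G, sigmas) {
  ll <- 0
  for (s in names(sigmas)) {
    rows <- df$station_id == s
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(c("1", fixed), collapse = "+"))),
      df[rows, ]
    )
    Z <- if (is.null(random_slope)) {
      matrix(1, sum(rows), 1)
    } else {
      cbind(1, df[[random_slope]][rows])
    }
    V <- Z %*% G %*% t(Z) + diag(sigmas[[s]]^2, sum(rows))
    r <- df[[response]][rows] - as.vector(X %*% beta)
    ll <- ll - 0.5 * (length(r) * log(2 * pi) +
      determinant(V, logarithm = TRUE)$modulus +
      sum(r * solve(V, r)))
  }
  as.numeric(ll)
}

# Closed-form variance-decomposition R2 from known components.
oracle_r2 <- function(var_fixed, var_random, var_resid) {
  tot <- var_fixed + var_random + var_resid
  c(
    r2_marginal = var_fixed / tot,
    r2_conditional = (var_fixed + var_random) / tot
  )
}
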