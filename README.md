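# pollenattrib

Detection and attribution of climate-driven trends in airborne pollen
seasons, for station-based pollen count networks.

Aero-allergen monitoring stations record 24-hour total pollen concentrations
(grains/m³) at irregular intervals, often only during an expected season.
`pollenattrib` turns such records into per-station-per-year season metrics,
detects continental trends in them with heteroscedastic mixed-effects models,
identifies their climate drivers by all-subsets AIC selection, and quantifies
how much of each trend is attributable to anthropogenic climate change (ACC)
using counterfactual temperature series derived from a climate-model
ensemble. Because real pollen-network data are access-restricted, the package
includes a synthetic-data generator that reproduces the study design with
planted ground truth, so the entire pipeline is verifiable by parameter
recovery.

## The model

For a metric $y_{st}$ at station $s$ in year $t$ (log10-transformed; square
root for the season start date), the trend-detection model is the linear
mixed model

$$g(y_{st}) = (\beta_0 + u_{0s}) + (\beta_1 + u_{1s})\,t + \varepsilon_{st},
\qquad (u_{0s}, u_{1s}) \sim N(0, G), \quad
\varepsilon_{st} \sim N(0, \sigma_s^2),$$

with station-specific random intercepts and slopes and a separate residual
variance per station, fit by maximum likelihood. The same structure with
climate covariates as fixed effects drives an all-possible-subsets AIC scan
over nine candidates (mean annual temperature `mat`, annual precipitation,
spring/summer temperature, precipitation and frost days, CO₂); models within
ΔAIC ≤ 3 of the best are plausible, and the one with the highest marginal R²
(Nakagawa variance decomposition) is selected.

For attribution, each climate model $i$ supplies an ACC signal — the 50-year
moving average of its annual temperature anomaly relative to an 1850–1880
baseline at each station — and a counterfactual series
$T^{noACC}_i = T^{obs} - \mathrm{ACC}_i$. The selected pollen–temperature
model predicts the metric under both series, and

$$\%\,\mathrm{ACC}_i = 100 \times
\frac{m_{wACC,i} - m_{noACC,i}}{m_{obs}}$$

is the percent ACC contribution of model $i$: the trend predicted under
observed temperatures minus the trend predicted under the no-ACC
counterfactual, relative to the observed metric trend (all slopes on the
transformed scale). The ensemble of per-model contributions is summarized by
its median and interquartile range over two windows (1990–2018, 2003–2018).

## Worked example

```r
library(pollenattrib)
library(dplyr)

truth <- truth_params(n_stations = 20, years = 1990:2018,
                      acc_fraction = 0.75, seed = 11)
bundle <- simulate_pollen_study(truth, n_models = 5)

metrics <- pollen_metrics(bundle$records, percentile = 30)
climate <- annual_covariates(
  extract_station_series(bundle$observed_climate, bundle$stations),
  co2 = bundle$co2
)

trend <- detect_trend(metrics, "annual_integral")
trend
#> <pollen_trend> annual_integral, 1990-2018 (580 obs, 20 stations)
#>   slope (log10 scale) 0.00260 +/- 0.00054 per yr, p = 1.5e-06
#>   change over record: 1.12e+03 [661, 1.57e+03] (18.3% [10.4%, 26.6%])

signal <- acc_signal(extract_station_series(bundle$ensemble, bundle$stations),
                     baseline = c(1850, 1880), window = 50)
acc <- counterfactual(transmute(climate, station_id, year, t_obs = mat), signal)
att <- ensemble_attribution(metrics, climate, acc,
                            metric_names = "annual_integral",
                            periods = list(c(1990, 2018)))
summary(att)
#> # A tibble: 1 × 7
#>   metric          period_start period_end n_models median   q25   q75
#>   <chr>                  <dbl>      <dbl>    <int>  <dbl> <dbl> <dbl>
#> 1 annual_integral         1990       2018        5   88.1  87.9  88.3
```

The generator planted ~21% integral growth per °C with 1 °C of warming over
1990–2018, 75% of it anthropogenic. The detected trend (+18.3% over the
record, p ≈ 1e-6) recovers the planted scale, and the ensemble median
contribution (≈ 88% against the planted 75%) is high by the amount this
seed's realized warming falls short of its planted trend — interannual
temperature noise moves the observed-trend denominator while the smoothed
forced signal stays at its planted value; across seeds the medians center on
the planted fraction (verified in the test suite). `autoplot()`
methods draw the station-spaghetti trend plot, the ensemble attribution
boxplot, and the ΔAIC selection profile; `tidy()`/`glance()` return
broom-style summaries of any fitted model.

`run_pipeline(pipeline_config(...), out_dir)` executes the whole chain —
simulate → metrics → climate → trends → selection → attribution — writing
every stage artifact as CSV/YAML plus a checksum manifest for reproducibility.

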