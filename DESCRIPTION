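Package: pollenattrib
Title: Detection and Attribution of Climate-Driven Trends in Airborne Pollen Seasons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continental-scale detection and attribution of trends in
    airborne pollen seasons. Derives pollen-season metrics (seasonal and annual
    pollen integrals, season start/end dates, daily concentration statistics)
    from sparse station count records, detects long-term trends with
    heteroscedastic random-slope mixed-effects models, selects climate drivers
    by all-subsets AIC with marginal and conditional R-squared, and attributes
    metric trends to anthropogenic climate change by contrasting trends
    predicted under observed temperatures with trends predicted under
    counterfactual no-forcing temperature series derived from a climate-model
    ensemble. Includes a synthetic-data generator that plants known temperature
    sensitivities, phenology shifts, and anthropogenic warming fractions so
    every stage of the pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
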