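Package: tempmort
Title: Extreme Temperature-Attributable Mortality Estimation and Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and projecting deaths attributable to
    extreme heat and extreme cold at the county-month level. Builds
    county-specific extreme-day exposures from daily mean temperature
    series, stabilises small-county mortality rates with spatial empirical
    Bayes smoothing, fits Poisson pseudo-maximum-likelihood regressions
    with absorbed county, month, and year fixed effects and
    heteroskedasticity-robust standard errors, computes counterfactual
    excess deaths with delta-method confidence intervals, and projects
    mid-century excess deaths across a climate-model ensemble under paired
    emissions and population scenarios. Includes a synthetic-study
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
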