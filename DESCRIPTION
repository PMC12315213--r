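Package: agroclimr
Title: Direct Climate-Change Risk Models for Agriculture on Daily Gridded Weather
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline of direct climate-change risk models for
    agricultural systems driven by daily climate series: threshold-exceedance
    crop hazard indices (heat stress, frost, extreme rainfall) over
    crop-sensitive calendar windows; a growing-degree-day phenology engine
    with FAO crop stages and a maturity-failure metric over multi-year time
    slices; a daily soil-water bucket with stage-dependent crop water demand
    that accumulates potential evapotranspiration deficit (PED); a fuzzy-logic
    crop suitability framework with trapezoidal memberships; empirical
    animal-health risk models (logistic occurrence models and a dairy
    temperature-humidity index); and time-slice/ensemble aggregation with
    change maps. A stochastic gridded daily weather generator (seasonal
    sinusoid plus AR(1) temperature, Markov-chain/gamma precipitation,
    per-scenario warming and precipitation perturbations across pseudo-ensemble
    members) stands in for downscaled climate projections so the whole
    pipeline is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2,
    knitr
Config/testthat/edition: 3
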