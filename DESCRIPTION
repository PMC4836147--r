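Package: pestclim
Title: Calibrated Temperature Ensembles and Thermal Performance Models for
    Crop Pest Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare how the spatiotemporal resolution of temperature
    data affects predictions of insect pest abundance in heterogeneous
    agricultural landscapes. Calibrates temperature datasets of three
    resolutions (monthly climatology, weather-station logger series, and
    in-canopy microclimate) into comparable monthly ensembles via classical
    additive time-series decomposition, propagates them through linear
    air-to-canopy microclimate models over a simulated crop-rotation mosaic,
    evaluates Sharpe-Schoolfield development and survival curves and a
    gamma-type fecundity curve over each ensemble, and relates the resulting
    performance summaries to monthly pest abundances with stepwise-AIC
    multiple linear regression, including temporal and elevation-gradient
    spatial validation. Ships a synthetic-data generator with known ground
    truth for every field-collected input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
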