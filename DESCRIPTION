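Package: rangewatch
Title: Rangeland Degradation Monitoring from Satellite-Style Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to monitor semi-arid rangeland degradation from multi-band
    reflectance time series and to ask whether long-term degradation arises
    from a loss of resistance to environmental shocks or a loss of recovery
    after them. Provides a fully synthetic savanna landscape generator with
    controllable resistance and recovery, spectral index computation
    (NDVI, EVI, BSI, MSAVI) with cloud masking, gap filling and seasonal
    compositing, harmonic phenology features, a bare-ground-index regression
    protocol (random forest, support vector and gradient boosted regressors
    under repeated cross-validation with a holdout partition), tertile-based
    resistance and recovery quantification with shock-year detection and
    two-way ANOVA comparisons, and a rainfall-adjusted long-term trend model
    with a spatially structured covariate regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    emmeans,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
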