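Package: stinterp
Title: Spatio-Temporal Interpolation of Monthly Pollutant Station Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpolating monthly pollutant-concentration series
    observed on a regular station grid, built around three spatio-temporal
    methods: inverse distance weighting with leave-one-station-out
    cross-validated power selection, bicubic spline smoothing with a synthetic
    boundary buffer that removes edge failures of scattered-data
    interpolation, and separable spatio-temporal kriging of penalized-spline
    detrended log10 residuals with lognormal bias-corrected
    back-transformation. Includes a synthetic PM2.5 field generator with
    seasonal, spatially correlated lognormal structure, a full evaluation
    harness (MAE, RMSE, MAPE, Nash-Sutcliffe, Kling-Gupta, index of
    agreement), rank-based method comparison (Friedman and Nemenyi tests) and
    residual spatial-autocorrelation diagnostics (Moran's I, Geary's C).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
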