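Package: heatrisk
Title: High-Resolution Urban Heat-Hazard Risk Mapping for the Elderly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical downscaling of coarse (1-km) daytime and night-time
    summer land surface temperature (LST) to a 100-m grid using fine-resolution
    NDVI as predictor, with one regression model per land-cover class (ordinary
    linear regression and penalized-spline generalized additive models), and
    combination of the resulting hazard layer with total-population exposure
    and elderly-population vulnerability layers into a Heat-related Elderly
    Risk Index (HERI) following Crichton's Risk Triangle. Includes a synthetic
    city-scene generator with known ground truth, per-risk-level zonal
    summaries (mean LST, coverage area, population frequency and density), and
    cross-city aggregation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'grids.R'
    'grid-io.R'
    'synthetic.R'
    'downscale.R'
    'population.R'
    'heri.R'
    'report.R'
    'pipeline.R'
    'data.R'
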