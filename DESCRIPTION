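Package: firetrack
Title: Wildfire Exposure Analysis for Tracked Wildlife Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies wildfire impact on wildlife populations from
    satellite active-fire detections, population density surfaces and GPS
    telemetry. Provides a regular-grid raster model with overlay algebra
    (rasterize, normalize, multiply, sum, resample), brightness-thresholded
    annual fire occurrence and intensity rasters, density-weighted exposure
    proxies and protected-area burn accounting, Ornstein-Uhlenbeck movement
    modelling with semi-variogram residency classification,
    autocorrelation-aware kernel home-range estimation, home-range burn
    statistics, and a seeded synthetic-scenario generator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
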