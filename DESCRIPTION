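Package: swathover
Title: Physics-Based Spatial Oversampling of Satellite Column Observations onto Administrative Polygons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates Level-2 satellite trace-gas column retrievals (e.g.
    tropospheric NO2 in 10^15 molecules/cm2) directly onto administrative
    polygons such as US census block groups. Implements physics-based
    oversampling, in which each satellite footprint is a 2-D super-Gaussian
    spatial response function, alongside the classical area-weighted polygon
    overlap scheme and a regular-grid baseline. Includes population-weighted
    exposure statistics by demographic group, relative-disparity metrics with
    polluted-day stratification, and a seeded synthetic scene generator
    (push-broom swath geometry, polygon tessellations, segregated
    demographics) so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
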