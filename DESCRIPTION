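Package: localADI
Title: Locally Calibrated Area Deprivation Index with Moving-Window
    Percentiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a 17-variable census-based area deprivation index
    (ADI) over small spatial units, recalibrates it as a percentile within
    distance-defined moving windows as well as over the whole study region,
    dichotomizes it at a top-percentile threshold, and validates the
    resulting deprivation flags against age-adjusted hospitalization rates
    via indirect standardization and Mantel-Haenszel stratified odds
    ratios. Includes a synthetic-geography simulator with controllable
    spatial structure (broad deprivation gradient plus local pockets) so
    the scale sensitivity of locally calibrated deprivation measures can be
    studied without restricted census or hospital-discharge data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
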