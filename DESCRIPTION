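Package: defolcal
Title: Calibrating Forest Defoliation Severity from Vegetation-Index Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Change-detection workflow for mapping insect defoliation severity
    in pine forests from paired pre- and post-outbreak multispectral
    surface-reflectance rasters. Computes five vegetation indices (MID, MSI,
    NDMI, NDVI, NBR) and their pre-minus-post differences (dVI), calibrates
    logistic models of defoliation fraction against 30 m ground-truth cells,
    scores fits with McFadden's pseudo R-squared, inverts the fitted curves
    into analytic classification thresholds, classifies rasters into four
    severity classes (nil, low, medium, high), and assesses agreement with
    observations via confusion-matrix accuracy metrics. Includes a synthetic
    scene generator with a known defoliation field so every stage is testable
    without satellite or aerial imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
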