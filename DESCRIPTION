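Package: plotpheno
Title: Per-Microplot Crop Trait Extraction from Orthomosaic and DSM Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Headless extraction of per-microplot crop height, vegetation
    coverage and volume-index traits from co-registered orthomosaic RGB and
    digital surface model (DSM) GeoTIFF pairs, as produced by SfM-MVS
    photogrammetry of field trials. Provides parametric plot-grid generation
    with Shapefile export, robust base-plane estimation from bare-ground
    rectangles or ridge crest lines (least-squares plane with a parallel
    downward shift excluding the deepest 5% of points), a maximum-entropy
    color classifier over RGB/HSV/Lab features for coverage, percentile
    height metrics (Height100/95/90/80), batch processing of time-series
    captures with CSV export, and a synthetic field generator with
    closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    foreign,
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
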