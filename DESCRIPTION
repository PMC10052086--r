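Package: lettucecv
Title: Canopy Computer-Vision Traits and Decision Indicators for Greenhouse Lettuce
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for RGB-D image analysis of greenhouse lettuce grown on
    spacing systems. Provides a synthetic top-down RGB-D scene generator with
    full per-plant ground truth, excess-green canopy segmentation with
    coverage and mean-IoU evaluation, RANSAC ground-plane fitting with
    per-pixel canopy heights and per-plant volume, the light-loss indicator
    for judging plant-spacing decisions, an area-by-height harvest indicator
    with quadratic fresh-weight calibration, and a per-square-metre net-profit
    ledger for greenhouse production economics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
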