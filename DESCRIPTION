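Package: cwsimap
Title: Crop Water Stress Index Mapping from Low-Cost Infrared Scans and
    RGB Canopy Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects crop water stress on small planted benches by fusing a
    scanned infrared temperature grid with an excess-green (ExG) plant
    segmentation of an RGB canopy image.  Provides a synthetic bench-scene
    generator with known ground truth (canopy geometry, true temperature
    field, treatment layout, environment and soil-moisture series), a
    conical field-of-view infrared scan simulator, ExG segmentation with
    classification metrics, leaf-temperature-map assembly and validation,
    non-water-stressed-baseline (NWSB) regression against vapor pressure
    deficit, clipped crop water stress index (CWSI) maps by the baseline
    and two-reference empirical methods, exponentially weighted moving
    average (EWMA) control charts for cycle monitoring, and a pipeline
    runner with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    lmtest,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
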