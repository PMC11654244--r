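Package: degronscreen
Title: Screen Analysis for Inducible-Degron Yeast Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for proteome-wide auxin-inducible-degron (AID)
    yeast library screens. Computes induced/uninduced relative-growth
    essentiality scores from arrayed colony grids with plate-median
    normalization, classifies per-strain fluorescence responsiveness from
    per-cell GFP intensities against an autofluorescence band, fits one-phase
    decay models to degradation time courses from imaging and immunoblots,
    recovers GO-slim terms from media-exclusive hit sets, aggregates
    responsiveness by subcellular compartment and abundance bins, and builds
    single-cell grid montages. Ships a synthetic-data generator that emulates
    every input, so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    png,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
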