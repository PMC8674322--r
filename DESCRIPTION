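Package: dtwsom
Title: Dynamic Time Warping Self-Organizing Maps for Diurnal Exposure Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery of typical within-day (diurnal) patterns in
    minute-resolution environmental sensor time series, such as residential
    temperature and fine particulate matter (PM2.5). Implements exact and
    Sakoe-Chiba band-constrained dynamic time warping (DTW) with warping-path
    extraction, three self-organizing map (SOM) variants (Euclidean SOM,
    DTW-matching SOM, and a full DTW-SOM whose weight updates follow the DTW
    alignment path), a sensor-data preprocessing chain (median smoothing,
    duplicate-sensor merging, gap truncation and interpolation, min-max
    scaling, day windowing, outcome matching), evaluation metrics
    (quantization error, grid-size tuning, Moore-neighbor distance,
    season-stratified cluster entropy, outcome-fraction overlays), and a
    synthetic minute-level exposure generator with known ground truth for
    end-to-end validation. Daily observations are carried in a
    SummarizedExperiment-derived container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
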