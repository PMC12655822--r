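Package: serscyto
Title: Multiplexed SERS Nanotag Unmixing and Single-Cell Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spectroscopic single-cell biomarker profiling with
    multiplexed surface-enhanced Raman scattering (SERS) nanotags. Simulates
    or ingests single-cell Raman spectra, preprocesses them (multi-segment
    iterative polynomial baseline correction, boxcar smoothing), deconvolves
    each spectrum into per-nanotag weight factors by classical least squares
    against a five-reporter reference library, classifies cells into breast
    cancer cell lines with a repeated stratified random-forest protocol, and
    selects two-dimensional t-SNE embeddings by Kullback-Leibler divergence
    and the Davies-Bouldin index. Includes a synthetic-data generator for the
    five-reporter nanotag system and an end-to-end pipeline that writes tidy
    report artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
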