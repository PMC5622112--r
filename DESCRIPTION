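Package: morphoscreen
Title: Label-Free Morphological Drug-Response Profiling from Bright-Field
    Single-Cell Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for label-free phenotypic drug screening from
    bright-field single-cell images of cells in flow. Reconstructs 2-D frames
    from 1-D line-scan waveforms, segments single cells, extracts a fixed
    548-feature morphological profile (geometry, granularity, intensity and
    texture families), discriminates drug-treated from untreated populations
    with a linear support vector machine under 10-fold cross-validation, and
    quantifies dose-dependent morphological change with the unbiased squared
    maximum mean discrepancy (MMD) estimator under a Gaussian kernel,
    including per-feature MMD ranking, MMD-guided feature elimination and
    single-model transfer across doses and experiments. A synthetic-data
    module generates line-scan streams, single-cell images and parametric
    feature tables with a configurable dose-response structure for
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    withr,
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
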