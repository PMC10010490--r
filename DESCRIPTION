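Package: VigorSpec
Title: Hyperspectral Chemometrics for Peanut Seed Vigor and SOD Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for assessing peanut seed vigor from
    visible/near-infrared hyperspectral images. Provides black/white
    reflectance correction and ENVI cube input/output, seed segmentation and
    per-seed mean spectra, Savitzky-Golay, multiplicative scatter correction
    and median-filter preprocessing, gradient-boosted-tree feature-band
    ranking, viability classification and partial-least-squares regression of
    superoxide dismutase (SOD) activity, germination vigor indices, and
    group-level correlation analysis. Includes a synthetic-data generator
    that emulates the spectral and phenotypic structure of accelerated-aging
    experiments so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    xgboost,
    randomForest,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    pheatmap,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
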