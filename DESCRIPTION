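Package: fnirsdoc
Title: Resting-State fNIRS Connectivity and Brain-Network Analysis for
    Disorders of Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for resting-state functional
    near-infrared spectroscopy (rs-fNIRS) assessment of residual
    consciousness: modified Beer-Lambert conversion of dual-wavelength
    intensity to hemoglobin concentration changes, band-pass filtering and
    PCA motion correction, three-rule channel quality control, Pearson
    functional-connectivity matrices with region-of-interest summaries,
    sparsity-thresholded binary brain networks with characteristic path
    length, clustering coefficient, global and local efficiency integrated
    over a sparsity grid (AUC), two-sample group statistics with effect
    sizes, and KNN/LDA leave-one-out classification of minimally conscious
    versus unresponsive-wakefulness patients.  Includes a synthetic
    two-group cohort generator with analytically known latent coupling so
    every stage is testable against ground truth, and a CRS-R behavioral
    score parser with rule-based diagnosis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    class,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
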