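Package: chctools
Title: Analysis of Chandelier-Cell Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium recordings of chandelier
    cells and pyramidal cells in mouse primary visual cortex. Implements
    fluorescence preprocessing (neuropil correction, moving-percentile
    delta-F/F, event-triggered averaging), circular-Gaussian orientation and
    direction tuning with circular-variance selectivity, a regularized
    factorized spatial-by-feature readout encoding model with most-exciting-
    input (MEI) synthesis and in-silico probes, population sparsity and
    linear-discriminant decoding with subsample permutation tests, virtual-
    tunnel analyses (position binning, Ward clustering with silhouette
    selection, Bhattacharyya-distance separability, visuomotor-mismatch
    correction, locomotion-onset detection), and chemogenetic-silencing
    statistics (locomotion modulation curves and index, circular-shift
    permutation tests). A synthetic-session generator with known ground
    truth supports parameter-recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
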