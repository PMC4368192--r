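Package: sqrfm
Title: Quantified Ratio Fingerprint Evaluation of Herbal Medicine Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for monitoring the batch-to-batch quality consistency of
    herbal medicines from multi-wavelength HPLC fingerprints. Implements the
    simple quantified ratio fingerprint method (SQRFM): the ratio similarity
    SF', the corrected quantified ratio similarity MF, the dissimilarity
    coefficient alpha, and the associated eight-grade quality classification;
    information-entropy weighting for fusing evaluations across detection
    wavelengths; marker-compound calibration, content quantification and the
    P5C geometric-mean content index; hydroxyl-radical scavenging-ratio and
    EC50 dose-response arithmetic; and a partial least squares regression
    (PLS1) spectrum-effect workflow with leave-one-out cross-validation and
    singular-point screening. Includes a synthetic peak-table generator with
    known ground truth and a bundled reference dataset of evaluation results
    for 27 production batches of Compound Bismuth Aluminate tablets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
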