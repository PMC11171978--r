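Package: tendonquant
Title: Quantitative Ultrasound Assessment of Tendons
Version: 0.1.0
Authors@R: person("tendonquant", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts a 51-variable quantitative descriptor from B-mode
    ultrasound images of tendons over five regions of interest: gray-level
    co-occurrence matrix (GLCM) and gray-level difference statistics (GLDS)
    texture features plus Haar wavelet sub-band statistics for the tissue
    quality and border regions, width/parallelism morphology from a polygonal
    tendon outline, and threshold-based bone segmentation features. Includes
    the companion reliability and validity pipeline: quadratic-weighted
    kappa, intraclass correlation coefficients, Kendall's W, ICC-based
    variable screening, random-intercept logistic mixed models with
    leave-one-subject-out cross-validation, and ROC/AUC model selection.
    Ships deterministic speckle-phantom and simulation generators so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    lme4,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
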