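Package: fcnet
Title: Partial-Correlation Network Modelling and Classification for
    Multi-Condition fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group analysis of functional brain networks across rest and
    attentive-tracking load conditions. Provides a synthetic cohort generator
    with controllable group, condition and nodal-variability effects; two-stage
    dual regression with an optional lesion-mask regressor and a frame-to-frame
    RMS head-motion metric; regularized partial-correlation (graphical lasso)
    network estimation with cross-validated penalty selection; shrinkage linear
    discriminant classification of condition and group with
    leave-one-subject-out cross-validation, balanced subsampling and
    permutation inference; and edgewise/nodewise mixed-design repeated-measures
    ANOVA with Benjamini-Hochberg FDR control, including nodal
    signal-variability (SDSA) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
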