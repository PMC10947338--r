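Package: vmatdose
Title: Deep-Learning Dose Prediction and Plan Quality Assurance for
    Female-Pelvis VMAT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts three-dimensional dose distributions for volumetric
    modulated arc therapy (VMAT) plans of the female pelvis and uses the
    predictions for plan quality assurance. Provides a seeded synthetic
    pelvis phantom cohort generator (anatomy masks plus an analytic dose
    model), a 16-channel preprocessing pipeline (CT normalization, target
    array, structure masks, resampling), a 3D dense dilated U-Net trained
    with a combined mean-squared-error and target dose-volume-histogram
    loss, overlapping-patch ensemble inference with D95 renormalization,
    and plan-quality analytics: DVH curves, conformity and homogeneity
    indices, dose-difference metrics, paired two-one-sided-test (TOST)
    equivalence testing, flagging of improvable plans, and automatic
    extraction of replanning objectives from a predicted dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
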