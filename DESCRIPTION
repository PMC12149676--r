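Package: adaptseg
Title: Prior-Conditioned Auto-Segmentation for Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation of mid-treatment head and neck CT conditioned on
    patient pre-treatment images and contours, for adaptive radiotherapy
    replanning.  Implements a 3D U-Net whose input channels can carry
    rigidly aligned pre-treatment data at inference time (general adaptive
    model), the comparator training regimes (reference and pooled
    patient-specific models), a mutual-information rigid-registration
    contour-propagation baseline, a synthetic paired-timepoint phantom
    cohort generator, label preprocessing (slice interpolation, connected
    component filtering), and the evaluation protocol: Dice similarity
    coefficient, mean surface distance, convergence audit and the corrected
    resampled t-test for cross-validated model comparison.
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
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
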