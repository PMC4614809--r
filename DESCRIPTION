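Package: hiparm
Title: Three-Dimensional Hip Muscle Moment Arms by Tendon Excursion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional muscle moment arms about the hip of a
    two-segment (pelvis + femur) musculoskeletal model using the
    tendon-excursion method and an exact geometric cross-product oracle.
    Implements a corrected three-degree-of-freedom joint-axis convention in
    which the flexion-extension axis stays fixed to the pelvis while the
    abduction-adduction and long-axis rotation axes rotate with the femur,
    together with a legacy pelvis-fixed-axes mode that reproduces the axis
    error of earlier comparative archosaur studies for quantitative
    comparison. Provides posture sweeps with femur-length normalization,
    muscle-function classification (including posture-dependent polarity
    switches), summed and mean functional-group statistics, biped-quadruped
    cohort contrasts, corrected-versus-legacy difference reports, synthetic
    model generators for validation, model file input/output, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
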