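Package: errorfields
Title: Likelihood-Weighted Haptic Error Augmentation for Movement Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for personalized error-augmented
    robotic movement training. Provides minimum-jerk reference trajectories for
    planar reaches under an angle-angle visuomotor transformation, per-direction
    statistical characterization of reaching errors as time-varying Gaussian
    likelihood fields, error-field (EF) and error-augmentation (EA) torque
    controllers with per-subject scale calibration and safety limiting, a
    synthetic trial-by-trial adapting learner to exercise the closed loop, and
    learning-curve analysis (non-negative exponential decay fits with
    cross-validation, change-in-error summaries, rank-based group statistics,
    and error-distribution shift measures).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
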