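Package: strideval
Title: Agreement Analysis for Foot-Mounted Inertial Sensors Against
    Motion Capture During Sprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the concurrent validity of foot-mounted
    inertial measurement unit (IMU) outputs against a laboratory criterion
    (3D motion capture plus force plates) during maximal sprinting. Provides
    a synthetic paired-trial generator with a configurable device error
    model, force-threshold gait-event detection and stride spatiotemporal
    metrics, kinematic signal derivation with residual-analysis filter
    cutoff selection, cross-device synchronization by RMSE minimization,
    and a method-comparison battery (MAE, RMSE, mean bias with 95% limits
    of agreement, log-ratio Bland-Altman, Spearman correlation with
    magnitude bands, normality and heteroscedasticity screens), together
    with an end-to-end validation pipeline and report builder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    nortest,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
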