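Package: hingecal
Title: Plug-and-Play Hinge-Joint Axis Calibration for Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the axis of a one-degree-of-freedom (hinge) joint in
    the intrinsic coordinate frames of two inertial measurement units
    attached to the joint's segments, from arbitrary motion.  The axis pair
    is estimated by weighted nonlinear least squares on the gyroscope
    angular-velocity constraint and the approximate accelerometer constraint
    of the rigid hinge, solved by Gauss-Newton with backtracking line search
    and a sign-pairing reinitialization.  Information-driven sample selection
    retains a bounded budget of informative gyroscope and accelerometer
    samples from arbitrarily long streams, and combined local
    (covariance-based, Monte-Carlo propagated) and global
    (sequential-consistency) uncertainty quantification reports when the
    estimate is reliable.  A rigid-body hinge-joint simulator with motion
    presets, Gaussian sensor noise and constant biases provides reproducible
    test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
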