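Package: swimkin
Title: Breaststroke Swimming Kinematics from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying lower-limb breaststroke swimming
    kinematics from raw inertial measurement unit (IMU) recordings. Fuses
    tri-axial gyroscope and accelerometer streams from eight body-worn
    sensors into orientation quaternions (gradient-descent attitude
    filter), performs static sensor-to-segment calibration, computes
    ankle, knee and hip joint angles, segments stroke cycles at maximum
    knee extension, and derives the full spatiotemporal and coordination
    parameter set: range of motion, cyclogram shape deviation (SSD), the
    angular component of the coefficient of correspondence (ACC),
    inter-limb phase shift, left-right asymmetry, and z-scored swim
    profiles. Includes nonparametric group statistics with epsilon-squared
    effect sizes, PCA plus k-means movement phenotyping, and a synthetic
    breaststroke IMU generator providing ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
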