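Package: gaitrod
Title: Drift-Free Leg Segment and Joint Angles from Dual-Accelerometer Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute leg-segment angles and sagittal-plane knee and
    ankle joint angles during gait from arrays of two accelerometers mounted on
    a rigid rod. Differencing the two sensors cancels gravity and translational
    acceleration, leaving signals proportional to the angular acceleration and
    to the squared angular velocity of the segment. A zero-phase bidirectional
    Butterworth low-pass filter divided by the negative squared cutoff
    frequency replaces the drift-prone double integration, with a steep
    high-pass stage for residual drift control and inclinometric
    self-calibration during quiet standing to restore the static offset.
    Includes a rigid-body forward model of walking (thigh, shank, foot) that
    generates synthetic accelerometer streams with known ground truth, cadence
    estimation from the acceleration spectrum, cadence-adaptive cutoff
    selection, agreement metrics, and cutoff-frequency sweep analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
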