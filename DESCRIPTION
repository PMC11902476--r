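Package: tapekin
Title: Kinematics of Tape-Like Unstable Training Surfaces from Anchor Angles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the kinematics (longitudinal position, lateral and
    vertical displacement, roll angle) of the loaded segment of a tape-like
    unstable base of support -- such as the tapes of a Sensopro Luna or a
    slackline -- from pitch, yaw, and roll angles measured near the two
    anchor points. The tape is modeled as an ideal rope between fixed
    anchors, so the loaded-point position follows from a closed-form ray
    intersection of the two anchor-segment directions. Includes a forward
    geometric simulator (ground-truth tape shapes, marker clouds, sensor
    noise, one-sided IMU pitch drift) used as synthetic-data generator and
    oracle, an offline signal-conditioning pipeline (zero-phase Butterworth
    filtering, resampling, exclusion rules, drift adjustments), rigid-body
    section reconstruction from motion-capture markers (Kabsch alignment,
    Tait-Bryan XYZ-intrinsic angles), parameter calibration, and an
    accuracy-evaluation toolkit (per-trial RMSE, percentile box statistics,
    position-conditioned error profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
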