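Package: armkit
Title: Quantifying Repetitive Arm Movement from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("armkit", "developers", email = "armkit@example.org", role = c("aut", "cre"))
Description: Implements the ARM (arm repetitive movement) analysis chain for
    arm-worn inertial measurement units: magnetometer-free sensor fusion of
    accelerometer and gyroscope streams, functional calibration of the humeral
    long axis, drift-free humeral elevation angles (0-180 degrees), amplitude-
    threshold detection of movement cycles, segmentation of active and resting
    bouts with a 7-second rest rule, repetitive-strain exposure metrics,
    validation against video-rated activity intervals, threshold sweeps, and
    paired Wilcoxon signed-rank comparison of dominant versus non-dominant
    arms. Includes a synthetic-data simulator that produces elevation traces
    and raw IMU streams with exact ground truth so every stage is testable
    without recorded data, and an 'arm' command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
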