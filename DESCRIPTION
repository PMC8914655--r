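Package: handmetrics
Title: Hand Kinematics and Haptic Wrist Measurement from Skeletal Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes clinically relevant hand measurements from skeletal
    tracking data: finger and hand sizes from a rigid-transform skeleton
    graph, wrist and finger ranges of motion from motion traces, and a
    simulated haptic force-ramp procedure for wrist deflection measurement.
    Includes a synthetic hand/motion generator with analytic ground truth,
    JSON-lines trace I/O, and device-agreement statistics (pooled
    repeatability SD, difference of means, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
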