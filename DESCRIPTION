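Package: gaitfga
Title: Automated Functional Gait Assessment from Markerless Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for markerless (keypoint-based) motion
    capture of clinical walking tests. Detects walking bouts and footsteps from
    anterior-posterior foot speed, computes step length, step width and head
    speed, scores Functional Gait Assessment (FGA) Conditions 2-6 from explicit
    speed and placement thresholds, and validates a markerless stream against a
    marker-based reference via time alignment, linear regression and
    Bland-Altman limits of agreement. Includes a synthetic gait simulator that
    provides exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    zoo,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
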