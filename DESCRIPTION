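Package: gazekit
Title: Video-Based Eye-Tracking Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis stack for video-based eye tracking built around the
    pupil/corneal-reflection technique: sub-pixel pupil and Purkinje-image
    detection in ocular images, linear least-squares gaze calibration from the
    pupil-to-glint vector, zero-phase Butterworth low-pass filtering of gaze
    traces, velocity-threshold saccade and fixation detection, and trial-level
    analysis of antisaccade and gap/overlap paradigms (latency, amplitude,
    validity classification, spatial accuracy). Includes a synthetic-session
    simulator with known ground truth (saccade kinematics, latency
    distributions, sampling jitter, frame loss, tracking-loss gaps, and
    rendered ocular images) for end-to-end validation, plus a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
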