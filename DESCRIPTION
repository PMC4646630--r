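Package: arcsleep
Title: Arm-Angle Sleep Detection from Raw Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Heuristic sleep detection for raw tri-axial wrist accelerometer
    data. Estimates the arm angle from rolling medians of the three
    acceleration axes, averages it into short epochs, and classifies maximal
    runs without posture change as sustained-inactivity bouts (candidate
    sleep). Sleep-log entries define nocturnal windows, are screened for
    implausible times (AM/PM confusion, swapped onset and waking) against the
    detected bouts, and yield per-night and weekly sleep summaries. Includes
    quadratic- and linear-weighted Cohen's kappa with asymptotic confidence
    intervals for ordinal agreement with questionnaire sleep duration,
    epoch-level validation against polysomnography hypnograms over a grid of
    time-window and angle-threshold parameters, and a seedable synthetic-data
    generator producing raw recordings, sleep logs with injected errors, and
    hypnograms with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lubridate,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
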