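Package: tremorvid
Title: Video-Based Kinematic Quantification of Essential Tremor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Markerless video motion analysis for essential tremor. Tracks
    anatomical points in rendered or recorded image sequences by normalized
    cross-correlation template matching, computes tremor kinematics for the
    postural ("wing-beat") and 15 cm line-drawing tasks (average velocity and
    acceleration, waves-per-second frequency, geometric-mean cycle amplitude,
    cumulative pen-tip path length, log10 pre/post treatment change), and
    implements the associated reliability and clinical-association statistics:
    one-way and two-way intraclass correlation coefficients with
    Shrout-Fleiss confidence intervals, minimal detectable change (MDC95 and
    MDC%), exact Wilcoxon signed-rank and Spearman rank tests, and the
    Weber-Fechner log-linear fit of clinical ratings to tremor amplitude.
    Includes a synthetic-data module that generates tremor trajectories,
    marker videos and rating cohorts with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
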