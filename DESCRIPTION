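Package: reachadapt
Title: Simulation and Analysis of Implicit Visuomotor Adaptation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sham-controlled studies of implicit visuomotor
    adaptation with center-out shooting reaches. Builds trial-by-trial
    experiment schedules for error-clamp, abrupt-rotation and
    gradual-rotation designs; simulates synthetic participant cohorts with a
    single-rate state-space learner and 125 Hz minimum-jerk pen trajectories;
    extracts per-trial kinematics (zero-phase Butterworth filtering, movement
    onset at 5% of peak radial speed, angular deviation at peak outward
    velocity, reaction and movement times); aggregates cycle-level adaptation
    metrics (baseline bias correction, learning-window determination by
    paired t-tests, adaptation rate and extent, aftereffect, decay residue,
    cross-day retention, trial-wise gradual learning rate); estimates passive
    decay rates by exponential fitting with a participant-level bootstrap;
    and compares groups with pooled t-tests, one-way ANOVA and default
    Jeffreys-Zellner-Siow Bayes factors, rendered as publication-style
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    ggplot2,
    rlang,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
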