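Package: gaitvideo
Title: Two-Dimensional Video-Based Gait Analysis from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative human gait analysis from single-camera
    sagittal-plane video that has been processed with a pose estimator
    (OpenPose BODY_25 keypoint JSON). Converts raw pixel keypoints into
    clean, metric, walking-frame trajectories (person selection, left/right
    limb-swap correction, gap filling, zero-phase Butterworth filtering,
    pixel-to-meter scaling), detects heel-strike and toe-off events from
    anterior-posterior ankle trajectories relative to the pelvis, computes
    spatiotemporal gait parameters (step, stance, swing and double-support
    times, step length, gait speed) and sagittal hip, knee and ankle angles
    normalized to the gait cycle, and provides between-system agreement
    statistics (paired differences, Pearson r, two-way intraclass
    correlations, repeated-measures ANOVA with Bonferroni post-hoc tests,
    cross-correlation at lag zero, walkway-position binning). A
    forward-kinematic synthetic walker with orthographic and pinhole camera
    models generates ground-truthed fixtures, including perspective
    (parallax) effects, so every stage can be validated without external
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    signal,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
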