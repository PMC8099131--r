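---
title: "Methods: video-based gait analysis and its validation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based gait analysis and its validation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitvideo)
```

## The measurement problem

A single stationary camera records a sagittal view of a person walking a
few meters. A pose estimator (the BODY_25 OpenPose model is the
supported dialect) returns, for every video frame, 25 pixel keypoints
with confidences. From this one stream the package estimates the
outcomes of a conventional gait assessment: heel-strike and toe-off
times, step/stance/swing/double-support times, step length, gait speed,
and sagittal hip, knee and ankle angle profiles over the gait cycle.
Because such estimates are only useful if their error scale is known,
the package also implements the full between-system agreement toolbox
(paired differences, Pearson r, two-way intraclass correlations,
repeated-measures ANOVA, lag-zero cross-correlation, walkway-position
binning) and a synthetic data generator with exact ground truth.

## Preprocessing model and parameters

Raw keypoints go through five steps, in a fixed order chosen so that
each step sees the cleanest possible input from the previous one:
walking-frame convention, limb-swap correction, gap filling, low-pass
filtering, scaling.

**Walking frame.** Pixel coordinates (origin top-left, y down) are
re-expressed with y up and x positive in the direction of travel. For a
left-side view this puts the origin at the lower-right image corner, for
a right-side view at the lower-left. All downstream quantities are
differences or angles, hence invariant to where the origin sits; the
transform is an involution, so applying it twice restores raw pixels.

**Missing data.** A keypoint is missing when its confidence is at or
below `confidence_threshold` (default 0 — only undetected keypoints,
which OpenPose encodes as zero-confidence zeros, are treated as
missing). The threshold is configurable because some users prefer to
discard low-confidence detections too.

**Limb-swap correction.** Pose estimators intermittently exchange the
left/right labels of the six leg keypoints. Human inspection of ankle
trajectories resolves these by continuity; the automated equivalent
chooses, per frame, the keep-or-swap assignment minimizing the summed
displacement of both ankles and knees relative to the previous corrected
frame. Two points per leg keep the decision well-conditioned at the
instants when the ankles cross (the knees are ~0.2 m apart then). A
forward and a backward pass are run and the globally cheaper solution
kept, so an ambiguous first frame cannot flip the whole bout. Frames
where both legs collapse onto one (confident ankles closer than
`eps_same_leg_px`, default 5 px — a free parameter, since no principled
value exists) have the lower-confidence leg marked missing. Every
altered frame is reported; the operation is idempotent.

**Gap filling.** Runs of at most `max_gap_frames` (default 2)
consecutive missing samples bounded by valid samples are linearly
interpolated (`zoo::na.approx` with `maxgap`); longer runs and runs
touching the record edge stay missing. At 25 Hz the 2-frame default
corresponds to gaps spanning up to 0.12 s between valid anchors. Valid
samples are never altered.

**Filtering.** A "zero-lag 4th-order low-pass Butterworth at 5 Hz" is
interpreted as a 4th-order design applied forward and backward
(`filtfilt` convention), giving zero net phase and an 8th-order
magnitude response; both order and cut-off are configurable. The
implementation designs coefficients with `signal::butter` and applies
them with odd-reflection padding and steady-state initial conditions,
so a constant series passes through bit-exactly (DC gain 1) and edge
transients are suppressed. Contiguous valid spans are filtered
independently; spans shorter than the warm-up length (3 × order
samples) are left unfiltered with a warning rather than corrupted.
Attenuation at 10 Hz (100 Hz sampling) exceeds 99%; content at ≤ 2 Hz
is passed with < 0.1% amplitude deviation.

**Scaling.** `s = reference_distance / reference_pixel_length` with the
pixel length measured horizontally between two landmarks on the floor at
the walking depth. The default reference distance (6.30 m) is the
walkway-tape separation of the public validation dataset this workflow
targets; it is a configuration value, not a constant of nature. The
model assumes walking perpendicular to the camera at fixed depth —
lens-distortion and depth-varying scale corrections are out of scope.

## Event detection

Heel-strike and toe-off are the positive and negative peaks of the
anterior–posterior ankle position relative to the pelvis (midhip
keypoint for pose; ASIS/PSIS midpoint for markers). The peak picker
needs two parameters that the underlying method leaves open; defaults
are derived from the gait range the package targets (step time ≈ 0.6 s):
minimum peak separation `min_period_s = 0.4` s and minimum prominence
`prominence_frac = 0.25` of the robust amplitude of the relative
trajectory (half its central 90% range — robust so that a few spikes do
not inflate the scale). Event time is the sample time of the peak frame;
no sub-frame interpolation is attempted because event errors are
conventionally reported in whole frames. Events within `boundary_s`
(default 0.4 s, on the order of the filter warm-up) of the record edge
are flagged and excluded from parameter summaries by default: a peak at
the very edge of a record cannot be certified as a true extremum.

## Spatiotemporal conventions

A step ends at a heel-strike and takes that side's label. Each
heel-strike row carries the stance that starts at it, the swing that
ends at it, and one double-support phase (to the contralateral toe-off)
— the definition is per step, not the per-stride sum of both phases.
Step length is the leading-minus-trailing ankle AP separation at the
heel-strike frame. Missing or out-of-order defining events leave `NA`
in the affected columns (logged), so per-parameter counts can differ —
as they do in real datasets. Gait speed is defined as mean step length
divided by mean step time, computed from the participant means rather
than per step. This makes `gait_speed == mean(step_length) /
mean(step_time)` an exact identity of the summary.

## Kinematic conventions

With hip→knee (thigh), knee→ankle (shank) and ankle→big-toe (foot)
vectors: the hip angle is the thigh's signed angle from vertical-down
(flexion positive); the knee angle is thigh-minus-shank orientation
(flexion positive); the ankle angle is the foot vector's signed angle
from the line perpendicular to the shank (dorsiflexion positive), which
equals its angle from horizontal when the shank is vertical. The ankle
convention reconciles a "0° is horizontal" neutral with a shank-based
reference; it is stated here as this package's convention rather than
inferred from any source. Angles are invariant to translation and
uniform scaling, so the pixel-to-meter factor cancels.

Strides (same-side heel-strike to heel-strike) are linearly resampled
to 101 points (0–100% in 1% steps — the field convention; the grid size
is configurable) and ensemble-averaged per leg. Resampling preserves
endpoint values exactly.

For marker data the same hip/knee/ankle/toe landmarks are used as for
keypoints. Regression-based hip-joint-center estimation is deliberately
not applied, so that both measurement streams share one angle
definition; against a mocap system that does use a regressed hip center
this contributes a small systematic hip-angle offset.

## Agreement statistics

The intraclass correlations are fixed to the McGraw–Wong two-way
single-measure forms: consistency `ICC(C,1) = (MS_R − MS_E) / (MS_R +
(k−1) MS_E)` and absolute agreement `ICC(A,1) = (MS_R − MS_E) / (MS_R +
(k−1) MS_E + (k/n)(MS_C − MS_E))`, with significance against zero via
`F = MS_R/MS_E` on `(n−1, (n−1)(k−1))` degrees of freedom. Since
`MS_C ≥ MS_E` whenever the systems carry a systematic offset,
`ICC(A,1) ≤ ICC(C,1)` up to numerical tolerance — agreement penalizes
bias, consistency forgives it. The repeated-measures ANOVA is the
classical within-subject one-way layout without sphericity correction
(none is conventional for a three-system comparison of this kind);
post-hoc comparisons are paired t-tests with p-values multiplied by the
number of pairs and capped at 1. Degenerate layouts (zero
between-system or zero residual variation) are resolved explicitly
(F = 0, p = 1, or F = ∞, p = 0) rather than left to floating-point
noise. Event lists from two systems are paired greedily by nearest
time within a tolerance (default half the median step time), which on
realistic jitter coincides with the exhaustive minimal-cost assignment
— the test suite verifies this against brute force. Walkway binning
(Start < −0.50 m, Middle within ±0.50 m, End > +0.50 m of the walkway
midpoint) keys on the mean anterior–posterior trunk position per gait
cycle; pose-derived coordinates have a corner origin, so
`compare_runs(walkway_origin=)` accepts the midpoint offset.

## The synthetic walker: what it emulates, and what it does not

The generator reproduces the recording conditions the workflow targets:
a ~5 m overground bout at 1.0 m/s (step time 0.6 s), 25 Hz video at
960×540 px from a sagittal camera ~3.3 m from the walking plane at
~1.3 m height, with a synchronized 100 Hz marker stream from the same
underlying motion and floor landmarks 6.30 m apart for scaling.

The walker is a pelvis-driven forward-kinematic chain: the pelvis
translates at gait speed while periodic joint profiles (legs half a
stride out of phase) place the leg keypoints. Profiles are sinusoid
sums with physiological amplitudes, not recorded human data: hip
8° ± ~14° with a 6° second harmonic, knee 32° ± 30°, ankle 0° ± 12°.
The second hip harmonic skews the relative ankle trajectory the way
ground contact does in real walking — slow backward drift in stance,
fast forward swing — placing toe-off ≈ 61% of the cycle after
heel-strike, so stance (0.73 s), swing (0.47 s) and double support
(0.13 s) land at healthy-adult values. The hip first-harmonic amplitude
is not a free parameter: it is calibrated by root finding so the
emergent step length equals the requested one, and an unreachable
request fails validation. Ground-truth events are the refined extrema
of the continuous relative-ankle trajectory, computed analytically and
independently of the pipeline's detector; with the default 0.6 s step
time at 25 Hz every true event falls exactly on a video frame, so event
recovery on clean input is exact rather than quantization-limited.

Two camera models are provided. Orthographic projection is the clean
baseline: a uniform scale, no perspective. The pinhole model projects
3D points through a camera at the configured distance; because the two
legs ride at different depths (±0.09 m mediolateral offset), their
magnifications differ and per-step lengths acquire position-dependent
errors that change sign across the walkway center, with opposite sign
for left- and right-heel-strike steps, and largely cancel in the bout
mean — the parallax phenomenology of real sagittal recordings, from
exact projection geometry.

Defect injection adds, at configured per-frame rates, Gaussian pixel
noise, keypoint dropouts (1–2-frame gaps), left/right label swaps and a
static tripod-like false person, each logged per frame so repairs are
auditable. The rates worth simulating in practice are the ones real
recordings exhibit: false persons in ~20% of frames and swapped limbs
in ~5%.

What the simulator does **not** model: OpenPose's actual error
distribution (its errors are structured, not i.i.d. Gaussian), gait
initiation and termination transients, soft-tissue and clothing
artifacts, lens distortion, and out-of-plane motion. Passing tests
therefore demonstrate that the pipeline's logic is correct and its
error floor small under controlled degradation — not that any given
real recording will reach the same accuracy.

## Numerical choices and degenerate inputs

* Peak prominence uses the 5–95% quantile range; flat relative
  trajectories yield no events plus a warning, as do records with less
  than one full oscillation.
* Tied person-selection candidates are broken by confident-keypoint
  count, then bounding-box area, then lowest index — deterministic
  across platforms. Person identity continuity is *not* assumed, since
  estimator ID assignment is not stable across versions.
* Frame order comes from the zero-padded numeric suffix of JSON
  filenames; non-contiguous indices are an error, never silently
  resampled.
* All randomness in the simulator and defect injection flows from one
  integer seed; the global RNG state is restored afterwards. Outputs
  embed an MD5 hash of the configuration for provenance, and identical
  configuration + seed give bit-identical output files.
* Test and validation problem sizes: the standard bout is 5 m
  (126 video frames, 8 steps); limb-swap repair statistics use a 40 m
  bout (~1000 frames, ~50 injected swaps at the 5% rate); statistical
  oracles run on random matrices of up to 10 subjects, where exhaustive
  computation is exact.

## Known limitations

Single-view 2D analysis cannot measure step width or frontal/transverse
angles. The fixed-depth scaling assumption biases spatial parameters
when subjects drift toward or away from the camera. Parallax is
characterized, not corrected — per-step spatial parameters near the
ends of the field of view carry systematic error, and averaging over a
bout only cancels it when the camera is centered on the walkway.
Pathological gait may violate the peak-picker's assumptions (e.g.,
shuffling gait with tiny relative-ankle excursions); the detector
parameters are exposed for such cases but have not been validated on
them.
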