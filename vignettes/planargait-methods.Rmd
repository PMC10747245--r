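---
title: "Methods: planar gait kinematics and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar gait kinematics and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planargait)
```

# The problem

Markerless, single-camera gait analysis estimates sagittal lower-limb
kinematics from 2D pose keypoints (OpenPose-style output) and must be
validated against a marker-based optical reference. The validation battery
this package implements compares, per joint and per body side, (a) the
whole joint-angle waveform over a gait cycle (mean absolute error with a
parametric 95% CI, and the coefficient of multiple correlation) and (b)
twelve discrete per-cycle parameters (trial-to-trial reproducibility via
ICC(1,3), AI-vs-reference Pearson correlation, and paired t-tests for fixed
error), with the customary clinical interpretation bands attached to each
cell. A particular question for a single laterally placed camera is whether
the limb opposite the camera — intermittently occluded by the near limb
during limb crossing — is measured less accurately than the camera-side
limb.

Because no raw laboratory recordings ship with the package, every stage is
exercised against a planar forward-kinematics simulator whose ground truth
(angles, events, keypoints) is known exactly.

# Joint-angle model

Landmarks are the 12 sagittal feature points (Neck, MidHip, and per side
Hip, Knee, Ankle, BigToe, Heel). Segment axes run proximal to distal:

* trunk = Neck to MidHip, thigh = Hip to Knee, shank = Knee to Ankle,
  foot = Heel to BigToe;
* hip flexion = signed trunk/thigh angle; knee flexion = signed
  thigh/shank angle; ankle dorsiflexion = signed shank/foot angle minus a
  fixed 90-degree neutral offset.

The hip is measured against the trunk axis, not the vertical, so trunk lean
moves the hip angle — this is the definition a 2D keypoint skeleton
affords. The 90-degree ankle offset is required for the foot axis
(heel-to-toe) to read 0 in neutral standing; without it a flat foot under a
vertical shank would read 90 degrees of "dorsiflexion".

Flexion and dorsiflexion are positive. Rather than hard-coding an image
orientation, the in-plane sign is resolved from the anatomy itself: the
sign of the cross product of the trunk-down axis with the mean
foot-forward axis. This makes all six waveforms invariant (to numerical
precision) under rotation, translation, scaling and mirroring of the
coordinate frame, properties the test suite checks directly. Peaks in the
extension/plantarflexion direction are reported as positive magnitudes of
the most-extended value, so signed waveforms coexist with all-positive
summary tables.

No static-trial offset calibration is applied to the keypoint stream by
default (`run_config(offset_calibration = TRUE)` enables a per-cycle mean
offset subtraction); a marker-based laboratory calibrates its own model,
but the pose stream has no analogous static trial.

# Preprocessing

Keypoints with confidence 0 are missing. Interior gaps of at most
`max_gap` frames (default 10, i.e. 83 ms at 120 Hz) are filled per
keypoint by linear interpolation and flagged as imputed; leading/trailing
gaps are never extrapolated, and any longer gap marks the side unusable
for that trial. Imputed frames are filtered like real ones and remain
flagged.

Coordinate trajectories (never angles) are smoothed with a zero-lag
Butterworth low-pass at 6 Hz. "Fourth-order zero-lag" is constructed the
way biomechanics pipelines conventionally do: a 2nd-order design applied
forward then backward (effective 4th order, -6.02 dB at the cutoff). The
alternative reading — a 4th-order design applied twice, effective 8th
order — is available as `convention = "design"`. Edge transients are
suppressed by odd-reflection padding with steady-state initial conditions,
which makes the DC gain exactly 1; the measured sinusoid attenuation
matches the designed digital filter's squared magnitude response (the
right oracle here is the digital design, not the analog prototype, because
bilinear-transform warping separates the two well below the Nyquist
frequency).

# Events, cycles and parameters

Ground contact is vertical GRF strictly above 20 N. An initial contact
(IC) requires at least 50 ms below threshold beforehand (a below-threshold
run touching the start of the recording qualifies, since pre-trial quiet
is unobservable); contact runs shorter than 100 ms are discarded as
artifacts; a toe-off requires 50 ms of quiet after the run. These debounce
windows are configuration-exposed because the 20 N rule alone is
ambiguous on real force plates.

A gait cycle runs IC to next IC of the same limb, and the same force-derived
interval is applied to both measurement streams. Waveforms are normalized to
the canonical 101-point grid (0–100% of cycle) by linear interpolation.
Event indices are 0-based; force samples convert to video frames by
`floor(sample * video_rate / force_rate)`. The stance share of a cycle is
kept at force-plate resolution (the toe-off is not floored to a video frame
before computing the stance percentage): flooring would shift the
stance/swing boundary by up to one frame (~0.8% of cycle), which visibly
biases the knee parameters whose extrema sit near that boundary.

The twelve parameters are: ankle peak dorsiflexion, peak plantarflexion
and excursion (whole cycle); knee peak flexion, peak extension and
excursion separately over the stance and swing slices; hip peak flexion,
peak extension and excursion (whole cycle). Excursion is max minus min
within the phase. Hip parameters use the whole cycle; nothing restricts
them to a phase. Cycles with more than 20% flagged frames, or a flagged
endpoint, are excluded with a logged reason, never silently imputed.

# Agreement statistics

* **MAE** — per cycle, the mean of |AI - reference| over the 101 grid
  points; averaged over a participant's cycles, then mean and
  t-distribution 95% CI across participants. An alternative granularity
  (MAE over the 12 discrete parameters) is behind
  `run_config(mae_granularity = "parameters")` since waveform-point MAE is
  an interpretation choice, not a law.
* **CMC** — the inter-protocol coefficient of multiple correlation with
  F = 2 protocols (AI and reference) per cycle:
  `sqrt(1 - [sum (Y_ft - Ybar_t)^2 / (T(F-1))] / [sum (Y_ft - Ybar)^2 /
  (FT-1)])`. When within-time dispersion exceeds total dispersion the
  radicand is negative and the value is *undefined*: it is reported as
  `NA` and excluded from means with a count, never clamped to 0. Per-cycle
  values are averaged per participant, then mean and SD across
  participants.
* **ICC(1,3)** — one-way random-effects, average-measures intraclass
  correlation over the participants-by-trials matrix of trial-mean
  parameters, computed from the ANOVA mean squares with Shrout–Fleiss
  F-bound confidence intervals, separately for each stream. Degenerate
  data yield ICC at or below 0 as computed, not floored.
* **Pearson r** and **paired t-tests** use the base-R implementations;
  the paired test resolves constant differences explicitly (identical
  pairs: t = 0, p = 1; constant non-zero difference: infinite t, p = 0).
  No multiple-testing correction is applied.
* **Bands** — AE: <=2 good, (2,5] acceptable, (5,10] tolerable, >10
  unacceptable; ICC: >=0.75 excellent, [0.4,0.75) fair to good, <0.4
  poor; CMC: [0.65,0.75) moderate, [0.75,0.85) good, [0.85,0.95) very
  good, [0.95,1] excellent, below 0.65 poor, undefined labelled as such.

Every statistic is verified in the test suite against an independent
brute-force transcription of its defining formula on batches of random
small inputs, plus Monte-Carlo checks of the ICC null distribution and the
CI coverage of the MAE interval.

# The synthetic-data generator

The generator is first-class, tested code, not a fixture. One
`gait_profile()` fixes cycle timing (default 1.1 s cycles at 120 Hz video
/ 1200 Hz force), six controllable peak angles (defaults near normative
adult walking: hip 30/11, knee 15 stance and 60 swing, ankle 14/14
degrees), stance fraction (0.6), segment lengths (trunk 0.50, thigh 0.41,
shank 0.42, foot 0.25 m — anthropometric plumbing, not claims), image
scale (200 px/m), walking speed (1.2 m/s) and the corruption knobs.

*Angle templates.* Each joint's waveform is a truncated Fourier series of
at most four harmonics. Hip and ankle use fixed base shapes affinely
rescaled so their extrema equal the profile fields exactly; the knee is a
sum of two raised-cosine-power bumps (loading response and swing) whose
two local maxima are fitted to the stance/swing peak fields by a small
iterative 2-by-2 solve. One deliberate consequence of a realistic
pre-swing flexion rise: the knee maximum over the *whole stance slice* is
the late-stance value (~30 degrees), not the ~15-degree loading-response
bump the `knee_stance_peak_flex` field controls. Round-trip checks
therefore compare extracted parameters against
`profile_parameter_targets()` — the extraction rules applied to the
analytic templates — rather than against raw field values.

*Forward kinematics.* The pelvis translates at constant speed with the
trunk vertical; thigh, shank and foot directions follow from the angle
definitions, inverted. The left limb is the right limb phase-shifted by
exactly half a cycle; cycle duration is rounded to an even frame count so
that this shift, and every initial contact, lands exactly on a video frame
(and hence a force sample), which is what makes exact event round-trips
possible. Feet are not constrained to the floor — this is a kinematic
stand-in, sufficient because every downstream quantity depends on angles,
not absolute foot height.

*GRF.* Each stance carries a double-bump envelope (peaks near body
weight, mid-stance valley ~0.73 body weight) with steep `sin^(1/4)`
loading/unloading edges, chosen so the trace crosses the 20 N threshold
within one force sample of the true contact boundary; swing is exactly
0 N. The left trace is offset half a cycle and includes the tail of the
stance preceding the first full left cycle, so a recording correctly
starts mid-stance on that side.

*Corruption.* Gaussian pixel noise (i.i.d., per coordinate) applies to
all visible keypoints; during limb-crossing frames (right/left knee or
ankle keypoints within 15 px) the five left-limb keypoints are dropped
with the stated probability by zeroing their confidence — the left limb is
the one a right-side camera loses. Defaults are noise 0 / dropout 0 (clean
reference conditions); the occlusion experiments use 2 px noise and 0.5
dropout. No published value exists for OpenPose keypoint jitter, so
`noise_sd` is an explicit simulation knob: at 200 px/m, 2 px is 1 cm of
joint-center jitter, a plausible magnitude.

*Cohorts.* `simulate_cohort()` draws per-participant peak angles with
between-subject SDs near published normative spreads (hip 6.0/5.0, knee
8.6/7.6, ankle 4.2/6.1 degrees), cycle duration SD 0.07 s, stance
fraction SD 0.015 and body mass SD 12 kg (clamped to physiologic ranges),
and re-jitters peaks across a participant's trials with SD 1.5 degrees so
ICC sees realistic trial-to-trial variability.

**What the simulator does not emulate:** soft-tissue artifact,
out-of-plane (frontal/transverse) motion and projection error, lens
distortion, ground-contact foot constraints, confidence values between 0
and 1, and pose-estimator failure modes other than occlusion dropout
(e.g. left/right identity swaps). Passing tests therefore demonstrate
correctness of the *pipeline arithmetic* under controlled corruption, not
field accuracy of any pose estimator.

# Numerical choices and degenerate inputs

* 0-based frame/sample indices everywhere; timestamps = index / rate.
* Coincident landmarks flag the frame invalid rather than producing a
  NaN axis; downstream cycles tolerate up to 20% flagged frames.
* The stance-slice boundary includes the grid point at the stance
  percentage (with a 1e-9 guard against floating-point shortfall).
* Undefined CMCs and non-positive ICCs are propagated as computed.
* Filtering requires a minimum run length (3 x (design order + 1) + 1
  samples); shorter valid runs pass through unfiltered rather than being
  mangled.
* All randomness flows from explicit integer seeds; identical seeds give
  byte-identical trials, reports and CSV outputs.

# Problem sizes used in the checks

The shipped verification runs use: single trials of 5 cycles for
round-trip checks; a 5-participant noiseless cohort for the
perfect-agreement limit; 120 random matrices per statistic for oracle
equivalence; 2000 replicates for the ICC null (50 subjects) and for MAE
CI coverage (n = 21); 50 random profiles for event-detection round trips;
and 21-participant cohorts across several seeds for the occlusion
asymmetry experiment. These sizes give stable Monte-Carlo estimates
(coverage to within ~1%, null-ICC mean to within ~0.01) while keeping a
full verification run in the minutes range.

# Known limitations

* All angles are planar projections; long-axis rotation and
  varus/valgus crosstalk are invisible by construction.
* The hip definition follows the trunk axis, so trunk lean aliases into
  hip flexion; the simulator holds the trunk vertical, real data need not.
* The occlusion model drops whole left-limb keypoint sets per frame;
  real pose estimators also mislocate points at partial occlusion.
* The CMC is reported undefined where its radicand exceeds 1; cohorts
  with near-constant waveforms (e.g. zero-amplitude profiles) will
  produce many undefined cells, by design.
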