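---
title: "Methods: dual-camera gaze estimation and synchrony analysis for face-to-face dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-camera gaze estimation and synchrony analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadgaze)
```

## The problem

Two people sit face to face, about 120 cm apart, with a small dual-camera
device between them.  Each camera watches one person and a neural detector
(out of scope here) reports, per frame, the image positions of four facial
landmarks (left eye, right eye, mouth, nose), per-eye pupil centers and
iris ellipses, an eye-open likelihood per eye, and a detection confidence.
`dyadgaze` implements everything downstream of that contract, in one shared
3D coordinate frame:

1. head pose of each person from the landmarks plus caliper-measured facial
   geometry;
2. 3D gaze of each eye from a two-sphere eye model;
3. the intersection of one person's gaze with the *other* person's face
   plane, with affine calibration and classification into facial areas of
   interest (AOIs: left eye, right eye, mouth, outside);
4. windowed time-lagged cross-correlation of the two gaze-angle series to
   quantify interpersonal gaze synchrony;
5. a ground-truth simulator that emulates the full detector contract, used
   to validate every stage end to end.

## World frame and cameras

The world frame has its origin at the midpoint between the two camera
centers, +y up, +z toward the participant, units cm.  Cameras are plain
pinhole models (no distortion; intrinsics are assumed rectified upstream),
with the usual computer-vision image convention (origin top-left, v down).
The default intrinsics, fx = fy = 1357 px at 1280 x 720, model the IMX219
sensor behind a 3.04 mm lens (1.12 um pixels) in 2x2-binned 720p mode.
The simulated rig follows the physical device: cameras back-to-back on a
3 cm pillar, eyes about 30.5 cm above the camera centers, each camera
tilted up at its person's face (about 27-30 degrees of elevation).

## Two-sphere eye model

The eyeball is a sphere of radius 1.2 cm rotating about a fixed
rotation center in the head; the iris is a circle of radius 0.6 cm whose
plane is normal to the optical axis.  Both radii are adult averages and
configurable per person.  Gaze is the axis from the rotation center through
the pupil; no fovea (kappa-angle) correction is applied.

Two estimators are provided:

* **Pupil offset** (default): the pupil pixel is back-projected and
  intersected with the eyeball sphere (near intersection — the visible
  pupil is on the camera-facing hemisphere); the gaze ray runs from the
  rotation center through that 3D point.
* **Iris unprojection**: the iris ellipse defines a viewing cone; the two
  planes cutting the cone in a 0.6 cm circle are found in closed form from
  the cone's eigendecomposition.  The two candidates (the classical
  two-fold ambiguity) are resolved by the head-facing direction with a
  camera-ward tie-break.  Disambiguation is reliable precisely because the
  camera views the face from ~30 degrees below the roughly horizontal gaze
  line; if the face ever pointed straight down the boresight the two
  candidates would be mirror images about the facing direction and
  genuinely confusable.

The ellipse estimator is used for validity checking by default because the
pupil-offset path is less sensitive to ellipse parameter noise; a config
switch selects either.

### Eye-center calibration

The per-person face-local eye-rotation-center offsets are estimated by
least squares over calibration fixations with known targets (a smoothly
moving nine-point pursuit on a screen), minimizing the mismatch between
pupil-derived gaze directions and center-to-target directions
(Levenberg–Marquardt, ftol/ptol 1e-12, at most 200 iterations, at least 6
frames).  One caveat matters: with a *static* head, the offset component
along the camera viewing ray is nearly unobservable from a single camera —
moving the center along the ray barely changes any pupil pixel — and pixel
noise then produces ~0.5-1 cm errors in that direction regardless of the
optimizer.  The calibration protocol therefore includes a
spontaneous-head-movement condition (smooth wander within about 12 degrees)
whose pose diversity rotates the face-local offset relative to the ray and
restores observability; under it, 0.5 px detector noise yields ~0.02-0.05 cm
recovery error.

## Head pose and face plane

Pose is fitted per frame by iterative re-projection least squares over the
rigid transform (axis-angle increment composed onto a warm start; the
previous frame's pose, or a closed-form frontal initialization whose depth
comes from the apparent inter-eye distance).  All four landmarks are used —
the nose, off the facial plane by ~2.4 cm, is what constrains out-of-plane
rotation — but the face *plane* is fitted through the eyes and mouth only,
with its origin at their centroid, u along the inter-eye axis, and the
normal oriented toward the partner.

## Filtering, exclusion, alignment

All detector series are smoothed by a per-coordinate constant-velocity
Kalman filter with exact handling of variable frame intervals
(white-acceleration process noise, default 200 px^2/s^3 for pixel series;
measurement noise from the data's known pixel noise, and 0 disables
smoothing entirely).  Frames are excluded *before* estimation: a frame is a
blink if either eye-open likelihood is strictly below 0.5, else an outlier
if detection confidence is strictly below 0.5; values exactly at a
threshold are kept.  When one person's gaze is intersected with the
partner's face, the partner's filtered 3D landmark series is linearly
interpolated to the gazer's timestamps; samples needing extrapolation or
bridging a gap over 0.1 s are invalid.

## AOI calibration and classification

The raw intersections inherit any systematic bias of the gaze estimate, so
each session is calibrated: the coordinate-wise medians of the
intersections over the last 4 s of the *first* left-eye, right-eye and
mouth trials are mapped exactly onto the median in-plane landmark
positions of the same windows by a 2D affine transform (three
correspondences, six unknowns); those three trials are excluded from all
statistics.  A calibrated point farther than 6.3 cm from every landmark is
`outside`; otherwise it takes the nearest landmark's label.  6.3 cm
corresponds to ~3 degrees of visual angle at the 120 cm interpersonal
distance, and the threshold is exposed both in cm and in degrees (via
`offset_from_angle()`).  Note that at a 60 cm conversational distance 3
degrees would instead be ~3.1 cm; the package treats the distance as a free
parameter and defaults the simulator to 120 cm, the distance at which the
two numbers are consistent.

Per-condition prediction rates use the last 4 s of each 5 s trial (prompts
take 0.4-0.6 s, so the window contains only settled fixations), median
across trials, then across participants; differences across conditions are
tested with Friedman rank tests (`stats::friedman.test`, chi-square
approximation, df = k - 1).

## Synchrony analysis

Gaze angles (azimuth/elevation of the cyclopean gaze direction in the world
frame, relative to the person's nominal facing — head plus eye movement
combined) are resampled to a 30 Hz grid.  For each trial, the synchronized
window pair is both persons' first 2 s of the trial; the null pair takes
the partner's window 5 s later.  Per window pair, Pearson correlations of
the overlapping segments are computed at every lag up to 1.5 s on the
grid step, per channel and averaged; the maximum and the absolute lag at
the maximum are kept (windows with under 10 overlapping samples per lag,
or zero variance, are skipped and logged).  Whether the original analysis
correlates a scalar angle or 2D components is an open choice; both modes
exist, channel-average is the default.  Medians per participant feed
paired Wilcoxon signed-rank tests (correlation and lag, synchronized vs
null).

The signed-rank statistic is W = min(W+, W-) with average ranks for ties
and zero differences dropped; the default p-value is the normal
approximation *without* continuity correction,
z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24), which reproduces the
small-sample reference values (n = 8: W = 1 gives p = .017, W = 0 gives
p = .012).  An exact mode via the signed-rank distribution is available;
the two agree to 0.01 wherever the exact p is below 0.10, though they
diverge by up to ~0.07 in the (decision-irrelevant) mid-range of W —
an intrinsic property of the uncorrected approximation, not a bug.

## The simulator and what it does (not) show

`simulate_dyad_session()` scripts both agents to saccade to the prompted
AOI on the partner's face after a per-trial instruction latency drawn
uniformly from 0.4-0.6 s, the second agent further delayed by a coupling
lag; `simulate_calibration_session()` scripts smooth pursuit of the
nine-point target.  Saccades are instantaneous relocations plus Gaussian
fixational jitter (azimuth/elevation, configurable sigma) — adequate for
angle time series, not a model of saccade kinematics.  Landmark and pupil
pixels receive additive Gaussian noise; iris ellipses are forward-projected
exactly (the projection of a circle through a pinhole camera, computed from
the viewing-cone conic).  Blinks are contiguous 100-300 ms dropouts of the
eye-open likelihood at a configurable event rate (default expectation
0.2 s x rate; a rate of 0.4 Hz drops ~8% of frames, matching typical
exclusion fractions); an alternative Bernoulli mode drops frames
independently at the same expected fraction, which makes excluded counts
exactly binomial for accounting checks.  The `outside` prompt is placed
10 cm lateral to the partner's eye midpoint.

What passing tests on this simulator demonstrate: the geometry and
statistics are internally consistent (noiseless streams reproduce
ground-truth gaze to < 0.1 degree and AOI labels exactly; known coupling
lags are recovered to one grid step; injected noise degrades accuracy
monotonically).  What they do not demonstrate: performance on real video,
where detector errors are non-Gaussian and temporally correlated, heads
translate as well as rotate, faces deform, and compliance with prompts is
imperfect.  Empirical accuracies of the physical system cannot be
reproduced here and are not asserted anywhere in this package.

## Problem sizes and numerical choices

Validation runs use 10-trial sessions for end-to-end identities, 40-frame
calibrations (20 seeds for noisy recovery), 60-trial sessions for
synchrony (8 dyads per replicate), and 1000 random circles for the
unprojection oracle; all sizes are package choices balancing statistical
resolution against desk-scale runtimes.  Parallel rays are rejected at
|dot| <= 1e-8; rays intersect planes only forward (t >= 0); affine
calibrations require |det| > 1e-10 and non-collinear correspondences
(twice-area test at 1e-10); the iris cone must have a genuinely elliptic
signature, otherwise the input is rejected as degenerate.  All simulator
output is byte-identical under a fixed seed.
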