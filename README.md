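# dyadgaze

Geometric and statistical toolkit for **simultaneous video-based gaze
estimation of two face-to-face interlocutors**, observed by a pair of
opposed cameras sharing one 3D world frame, and for **interpersonal gaze
synchrony analysis** on the resulting gaze-angle time series.

It is written for researchers studying face-to-face social interaction who
record both partners with a compact dual-camera device and run neural
detectors (landmarks, pupils, iris ellipses, blink likelihoods) upstream.
`dyadgaze` takes over at the detector output and provides:

- **Head pose** per frame from the four facial landmarks plus
  caliper-measured facial geometry (re-projection least squares).
- **3D gaze** from a two-sphere eye model: the gaze ray runs from the eye
  rotation center `c` through the 3D pupil `p`, where `p` is the near
  intersection of the back-projected pupil pixel with the eyeball sphere
  `‖x − c‖ = R` (R = 1.2 cm).  Iris-ellipse unprojection (the two circular
  sections of the viewing cone, resolved by head facing) is provided as an
  independent estimator and validity check.  Rotation centers are
  calibrated per person from smooth-pursuit fixations.
- **Face-plane AOI classification**: the partner's face plane is fitted
  through their eyes and mouth; gaze is intersected with it
  (`t = (p₀ − o)·n / d·n`), affinely calibrated from the first left-eye /
  right-eye / mouth trials, and labeled by the nearest-landmark rule with
  an *outside* threshold of 6.3 cm ≈ `atan(6.3/120) ≈ 3°` of visual angle
  at a 120 cm interpersonal distance.
- **Synchrony**: windowed time-lagged cross-correlation of the two
  persons' gaze angles (azimuth/elevation, head + eye), synchronized
  same-trial windows vs null windows offset by 5 s, medians per
  participant, paired Wilcoxon signed-rank tests
  (`z = (W − n(n+1)/4)/√(n(n+1)(2n+1)/24)`, W = min rank sum).
- **Kalman smoothing** (constant velocity, per coordinate), blink/outlier
  exclusion by likelihood thresholds, and cross-camera linear
  interpolation of time series.
- A **ground-truth dyad simulator** emulating the whole detector contract
  (pinhole projections of landmarks, pupils and iris ellipses for two
  opposed cameras, scripted AOI prompts over 60 × 5 s trials, instruction
  latencies, coupling lags, noise, blinks), used by the test suite to
  validate every stage end to end.

See `vignettes/dyadic-gaze-methods.Rmd` for the full model description,
parameter defaults, and limitations.

## Worked example

Simulate a noiseless 10-trial dyad session, run the full estimation
pipeline, and compare against ground truth:

```r
library(dyadgaze)

cfg   <- scene_config(seed = 42)                 # 120 cm dyad, 30 Hz
sched <- make_trial_schedule(10, seed = 42)      # 10 x 5 s AOI prompts
sim   <- simulate_dyad_session(cfg, sched, include_iris = FALSE)

res <- run_dyad_pipeline(sim$obs_p, sim$obs_e, sched, cfg,
                         measurement_noise_px = 0)
err <- gaze_error_vs_truth(res$p$gaze, sim$ground_truth, "participant")

cat("median gaze error (deg):", round(err$median_error_deg, 4), "\n")
cat("median correct AOI rate:", res$p$rates$median_correct, "\n")
print(round(res$p$rates$table, 3))
```

prints

```
median gaze error (deg): 0
median correct AOI rate: 1
           label
condition   left_eye right_eye mouth outside
  left_eye         1         0     0       0
  right_eye        0         1     0       0
  mouth            0         0     1       0
  outside          0         0     0       1
```

i.e. with noiseless detector streams the pipeline reproduces the true gaze
directions exactly and classifies every analysis-window sample into the
prompted facial area (rows are prompted conditions, columns assigned
labels, entries median per-trial fractions).

A synchrony analysis on a dyad whose responses are coupled with a 0.3 s
lag, under 1° fixational jitter:

```r
cfg   <- scene_config(angle_noise_deg = 1, seed = 7)
sched <- make_trial_schedule(60, seed = 7)
sim   <- simulate_dyad_session(cfg, sched, coupling_lag_s = 0.3,
                               project = FALSE)
mk <- function(id) {
  g <- sim$ground_truth[sim$ground_truth$person_id == id, ]
  gaze_angle_series(id, g$timestamp, g$gaze_az_deg, g$gaze_el_deg)
}
win <- synchrony_windows(build_window_pairs(mk("participant"),
                                            mk("experimenter"), sched))
str(summarize_per_participant(win)[1:4])
#> $ median_correlation_sync  : num 0.521
#> $ median_correlation_unsync: num 0.309
#> $ median_lag_sync          : num 0.3
#> $ median_lag_unsync        : num 1.33
```

The synchronized windows correlate more strongly than the 5-s-offset null
windows, and the lag of maximum correlation recovers the injected 0.3 s
coupling exactly (one 30 Hz grid step of resolution).

## Command line

A thin CLI over the same functions lives at `inst/cli/dyadgaze.R`:

```sh
Rscript inst/cli/dyadgaze.R simulate  --out-dir out --seed 1 --trials 60
Rscript inst/cli/dyadgaze.R estimate  --out-dir out
Rscript inst/cli/dyadgaze.R synchrony --out-dir out --lag 0.3
```

Stages communicate through documented CSV/YAML/JSON artifacts
(frame series, schedules, camera and face-metrics configs, summaries).

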