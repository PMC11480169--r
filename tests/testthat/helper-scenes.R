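# Shared fixtures, built in code.

test_camera <- function(fx = 1357, fy = 1357, cx = 640, cy = 360,
                        center = c(0, 0, 0), target = c(0, 0, 100)) {
  camera_look_at("test_cam", center, target, fx, fy, cx, cy)
}

# Identity-extrinsics camera (world frame == camera frame).
identity_camera <- function(fx = 1000, fy = 1000, cx = 0, cy = 0) {
  camera_model("id_cam", fx, fy, cx, cy, diag(3), c(0, 0, 0))
}

random_rotation <- function() {
  rodrigues(stats::rnorm(3))
}

# Random 3D circle in front of `cam`, roughly facing it.
random_facing_circle <- function(cam, radius = 0.6) {
  ctr <- c(stats::runif(1, -15, 15), stats::runif(1, -10, 10),
           stats::runif(1, 40, 120))
  o <- camera_center(cam)
  n <- (o - ctr) / sqrt(sum((o - ctr)^2))
  w <- stats::rnorm(3, 0, 0.25)               # tilt away from boresight
  n <- as.numeric(rodrigues(w) %*% n)
  if (sum(n * (ctr - o)) > 0) n <- -n
  circle_candidate(ctr, n, radius)
}

# Calibration-session frames (pupil pixels + pose + target) for eye-center
# estimation, subsampled to ~`n` distinct pursuit targets.
calibration_frames <- function(session, n = 40, poses = NULL) {
  idx <- round(seq(1, length(session$times), length.out = n))
  if (is.null(poses)) poses <- session$poses
  lapply(idx, function(i) list(
    pupil_px = list(
      left = c(session$obs$pupil_left_u[i], session$obs$pupil_left_v[i]),
      right = c(session$obs$pupil_right_u[i], session$obs$pupil_right_v[i])),
    pose = poses[[i]],
    target = session$target_world[i, ]))
}

# Ground-truth gaze-angle series for one person of a simulated dyad.
gt_angle_series <- function(sim, person_id) {
  g <- sim$ground_truth[sim$ground_truth$person_id == person_id, ]
  gaze_angle_series(person_id, g$timestamp, g$gaze_az_deg, g$gaze_el_deg,
                    valid = !g$blink)
}

# Per-participant synchrony medians for one simulated dyad.
dyad_synchrony_medians <- function(seed, coupling_lag_s = 0.3,
                                   angle_noise_deg = 1, n_trials = 60) {
  cfg <- scene_config(angle_noise_deg = angle_noise_deg, seed = seed)
  sched <- make_trial_schedule(n_trials, seed = seed)
  sim <- simulate_dyad_session(cfg, sched, coupling_lag_s = coupling_lag_s,
                               project = FALSE)
  win <- synchrony_windows(build_window_pairs(
    gt_angle_series(sim, "participant"), gt_angle_series(sim, "experimenter"),
    sched))
  summarize_per_participant(win)
}
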