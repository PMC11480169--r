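# Ground-truth dyad simulator.  Emulates the detector-level output of two
# opposed cameras watching two face-to-face interlocutors: facial landmark
# pixels, pupil centers, iris ellipses, eye-open likelihoods and detection
# confidences, together with the ground truth (poses, gaze directions,
# prompted targets, face-plane intersections) that generated them.
#
# Geometry emulated: cameras centrally mounted back-to-back on a 3 cm
# pillar, eyes about 30.5 cm above the camera centers (cameras at 29.5 cm
# over the table, eyes at about 60 cm), interpersonal distance 120 cm by
# default, cameras tilted up toward the faces.

#' Scene configuration for the dyad simulator
#'
#' @param interpersonal_distance_cm face-to-face distance (default 120).
#' @param frame_rate_hz camera frame rate (default 30).
#' @param eye_height_cm eye height above the camera centers (default 30.5).
#' @param camera_separation_cm distance between the two opposed camera
#'   centers along the interpersonal axis (default 3).
#' @param fx,fy,cx,cy camera intrinsics, pixels; defaults model the
#'   IMX219 sensor with a 3.04 mm lens (1.12 um pixels) in 2x2-binned
#'   720p mode.
#' @param landmark_noise_px additive Gaussian noise on landmark pixels.
#' @param pupil_noise_px additive Gaussian noise on pupil pixels.
#' @param angle_noise_deg fixational gaze jitter (az/el), degrees.
#' @param blink_rate_hz rate of blink events (contiguous 100-300 ms
#'   dropouts of the eye-open likelihood); default 0.
#' @param blink_mode `"events"` (default; contiguous dropouts, temporally
#'   realistic) or `"bernoulli"` (each frame independently dropped with
#'   probability `0.2 * blink_rate_hz`, the events-mode expected fraction;
#'   gives exactly binomial counts, useful for exclusion accounting).
#' @param metrics_p,metrics_e [face_metrics()] of participant/experimenter.
#' @param eye_params an [eye_model_params()] (true eye-center offsets).
#' @param seed RNG seed; a fixed seed makes simulator output byte-identical.
#' @return object of class `scene_config` with derived members `camera_p`,
#'   `camera_e` ([camera_model()]s) and `pose_p`, `pose_e` ([head_pose()]s).
#' @export
scene_config <- function(interpersonal_distance_cm = 120,
                         frame_rate_hz = 30,
                         eye_height_cm = 30.5,
                         camera_separation_cm = 3,
                         fx = 1357, fy = 1357, cx = 640, cy = 360,
                         landmark_noise_px = 0, pupil_noise_px = 0,
                         angle_noise_deg = 0, blink_rate_hz = 0,
                         blink_mode = c("events", "bernoulli"),
                         metrics_p = default_face_metrics("participant"),
                         metrics_e = default_face_metrics("experimenter"),
                         eye_params = eye_model_params(),
                         seed = 1) {
  stopifnot(interpersonal_distance_cm > 0, frame_rate_hz > 0,
            landmark_noise_px >= 0, pupil_noise_px >= 0,
            angle_noise_deg >= 0, blink_rate_hz >= 0)
  blink_mode <- match.arg(blink_mode)
  d <- interpersonal_distance_cm / 2
  s <- camera_separation_cm / 2
  pose_p <- head_pose(.facing_rotation(c(0, 0, -1)), c(0, eye_height_cm, d))
  pose_e <- head_pose(.facing_rotation(c(0, 0, 1)), c(0, eye_height_cm, -d))
  camera_p <- camera_look_at("cam_p", c(0, 0, s), pose_p$translation,
                             fx, fy, cx, cy)
  camera_e <- camera_look_at("cam_e", c(0, 0, -s), pose_e$translation,
                             fx, fy, cx, cy)
  structure(list(interpersonal_distance_cm = interpersonal_distance_cm,
                 frame_rate_hz = frame_rate_hz, eye_height_cm = eye_height_cm,
                 landmark_noise_px = landmark_noise_px,
                 pupil_noise_px = pupil_noise_px,
                 angle_noise_deg = angle_noise_deg,
                 blink_rate_hz = blink_rate_hz, blink_mode = blink_mode,
                 metrics_p = metrics_p, metrics_e = metrics_e,
                 eye_params = eye_params, seed = seed,
                 camera_p = camera_p, camera_e = camera_e,
                 pose_p = pose_p, pose_e = pose_e),
            class = "scene_config")
}

#' Default caliper-style facial metrics
#'
#' Adult-average landmark layout in the face-local frame (origin midway
#' between the eyes, +x left-to-right eye, +y up, +z out of the face), cm.
#'
#' @param person_id label.
#' @return a [face_metrics()].
#' @export
default_face_metrics <- function(person_id) {
  face_metrics(person_id, head_width = 15.2,
               landmark_offsets = list(left_eye  = c(-3.1, 0, 0),
                                       right_eye = c( 3.1, 0, 0),
                                       mouth     = c(0, -7.2, 0.3),
                                       nose      = c(0, -3.2, 2.4)))
}

# --- internal helpers -------------------------------------------------------

# Blink mask over frame times: Poisson events of 100-300 ms, or independent
# per-frame Bernoulli drops matching the events-mode expected fraction.
.blink_mask <- function(times, rate_hz, mode = "events") {
  mask <- rep(FALSE, length(times))
  if (rate_hz <= 0 || length(times) == 0) return(mask)
  if (mode == "bernoulli")
    return(stats::runif(length(times)) < 0.2 * rate_hz)
  total <- max(times) - min(times)
  n <- stats::rpois(1, rate_hz * total)
  if (n == 0) return(mask)
  on <- stats::runif(n, min(times), max(times))
  dur <- stats::runif(n, 0.1, 0.3)
  for (i in seq_len(n)) mask <- mask | (times >= on[i] & times < on[i] + dur[i])
  mask
}

# Perturb unit direction rows by Gaussian az/el jitter (degrees) in `ref`.
.jitter_dirs <- function(dirs, sigma_deg, ref) {
  if (sigma_deg <= 0) return(dirs)
  ang <- dirs_to_angles(dirs, ref)
  az <- (ang[, 1] + stats::rnorm(nrow(dirs), 0, sigma_deg)) * pi / 180
  el <- (ang[, 2] + stats::rnorm(nrow(dirs), 0, sigma_deg)) * pi / 180
  local <- cbind(cos(el) * sin(az), sin(el), cos(el) * cos(az))
  local %*% t(ref)
}

# Per-frame fixated target points: switch_times (one per trial) move the
# fixation to targets[i, ]; before the first switch the initial target holds.
.target_track <- function(times, switch_times, targets, initial) {
  idx <- findInterval(times, switch_times)
  out <- matrix(initial, length(times), 3, byrow = TRUE)
  sel <- idx > 0
  out[sel, ] <- targets[idx[sel], , drop = FALSE]
  out
}

# World positions of a person's AOI targets on the partner's face.
.partner_targets <- function(pose, metrics) {
  lw <- landmark_matrix(metrics) %*% t(pose$rotation) +
    matrix(pose$translation, 4, 3, byrow = TRUE)
  rownames(lw) <- names(metrics$landmark_offsets)
  mid <- (lw["left_eye", ] + lw["right_eye", ]) / 2
  rbind(left_eye = lw["left_eye", ], right_eye = lw["right_eye", ],
        mouth = lw["mouth", ], outside = mid + 10 * pose$rotation[, 1],
        center = mid)
}

# Project one person's observation stream (landmarks, pupils, iris) into
# the observing camera.  gaze_dirs_l/r: n x 3 unit dirs per eye.
.project_person <- function(camera, pose, metrics, eye_params, times,
                            gaze_l, gaze_r, landmark_noise_px,
                            pupil_noise_px, blink, include_iris = TRUE) {
  n <- length(times)
  lw <- landmark_matrix(metrics) %*% t(pose$rotation) +
    matrix(pose$translation, 4, 3, byrow = TRUE)
  lm_px <- project(camera, lw)           # 4 x 2, pose static within a call
  ecl <- as.numeric(pose$rotation %*% eye_params$eye_center_offsets$left +
                      pose$translation)
  ecr <- as.numeric(pose$rotation %*% eye_params$eye_center_offsets$right +
                      pose$translation)
  re <- eye_params$eyeball_radius
  ri <- eye_params$iris_radius
  pupil_l <- matrix(ecl, n, 3, byrow = TRUE) + gaze_l * re
  pupil_r <- matrix(ecr, n, 3, byrow = TRUE) + gaze_r * re
  ppx_l <- project(camera, pupil_l)
  ppx_r <- project(camera, pupil_r)
  noise <- function(m, s) if (s > 0) m + stats::rnorm(length(m), 0, s) else m
  obs <- data.frame(camera_id = camera$camera_id, timestamp = times)
  lm_names <- c("left_eye", "right_eye", "mouth", "nose")
  for (i in seq_along(lm_names)) {
    obs[[paste0(lm_names[i], "_u")]] <- noise(rep(lm_px[i, 1], n),
                                              landmark_noise_px)
    obs[[paste0(lm_names[i], "_v")]] <- noise(rep(lm_px[i, 2], n),
                                              landmark_noise_px)
  }
  obs$pupil_left_u <- noise(ppx_l[, 1], pupil_noise_px)
  obs$pupil_left_v <- noise(ppx_l[, 2], pupil_noise_px)
  obs$pupil_right_u <- noise(ppx_r[, 1], pupil_noise_px)
  obs$pupil_right_v <- noise(ppx_r[, 2], pupil_noise_px)
  iris_cols <- c("u", "v", "a", "b", "theta")
  for (eye in c("left", "right"))
    for (cc in iris_cols) obs[[paste0("iris_", eye, "_", cc)]] <- NA_real_
  if (include_iris) {
    h <- sqrt(re^2 - ri^2)
    for (i in seq_len(n)) {
      el <- project_circle(camera, circle_candidate(ecl + h * gaze_l[i, ],
                                                    gaze_l[i, ], ri))
      er <- project_circle(camera, circle_candidate(ecr + h * gaze_r[i, ],
                                                    gaze_r[i, ], ri))
      obs$iris_left_u[i] <- el$center[1];  obs$iris_left_v[i] <- el$center[2]
      obs$iris_left_a[i] <- el$semi_axes[1]; obs$iris_left_b[i] <- el$semi_axes[2]
      obs$iris_left_theta[i] <- el$angle
      obs$iris_right_u[i] <- er$center[1]; obs$iris_right_v[i] <- er$center[2]
      obs$iris_right_a[i] <- er$semi_axes[1]; obs$iris_right_b[i] <- er$semi_axes[2]
      obs$iris_right_theta[i] <- er$angle
    }
  }
  obs$eye_open_likelihood_left <- ifelse(blink, 0.05, 1)
  obs$eye_open_likelihood_right <- ifelse(blink, 0.05, 1)
  obs$detection_confidence <- 1
  obs
}

# --- sessions ---------------------------------------------------------------

#' Simulate a face-to-face dyad session
#'
#' Both agents saccade to the prompted facial area of the partner after a
#' per-trial instruction latency drawn uniformly from `latency_range`; the
#' second agent (experimenter) is additionally delayed by `coupling_lag_s`.
#' Fixational jitter, landmark/pupil pixel noise and blinks are injected
#' per the configuration.
#'
#' @param config a [scene_config()].
#' @param schedule a [trial_schedule()].
#' @param coupling_lag_s extra response delay of the experimenter, s.
#' @param latency_range instruction latency bounds, s (default 0.4-0.6).
#' @param project generate camera observation streams (set `FALSE` for
#'   ground-truth-only runs, e.g. synchrony power studies).
#' @param include_iris forward-project iris ellipses (slower; default TRUE).
#' @return list with `obs_p`, `obs_e` (frame-series data frames, `NULL`
#'   when `project = FALSE`) and `ground_truth` (long data frame: one row
#'   per frame per person with fixated condition, gaze angles, gaze
#'   direction, target point and true partner-face-plane intersection).
#' @export
simulate_dyad_session <- function(config, schedule, coupling_lag_s = 0,
                                  latency_range = c(0.4, 0.6),
                                  project = TRUE, include_iris = TRUE) {
  set.seed(config$seed)
  rate <- config$frame_rate_hz
  t_end <- max(schedule$start_s + schedule$duration_s)
  times <- seq(0, t_end - 1e-9, by = 1 / rate)
  lat <- stats::runif(nrow(schedule), latency_range[1], latency_range[2])
  sw_p <- schedule$start_s + lat
  sw_e <- sw_p + coupling_lag_s

  tg_p_tab <- .partner_targets(config$pose_e, config$metrics_e)  # P looks at E
  tg_e_tab <- .partner_targets(config$pose_p, config$metrics_p)
  tg_p <- .target_track(times, sw_p,
                        tg_p_tab[schedule$condition, , drop = FALSE],
                        tg_p_tab["center", ])
  tg_e <- .target_track(times, sw_e,
                        tg_e_tab[schedule$condition, , drop = FALSE],
                        tg_e_tab["center", ])

  gt <- list()
  person_state <- list()
  for (who in c("p", "e")) {
    pose <- config[[paste0("pose_", who)]]
    metrics <- config[[paste0("metrics_", who)]]
    tg <- if (who == "p") tg_p else tg_e
    sw <- if (who == "p") sw_p else sw_e
    ecl <- as.numeric(pose$rotation %*%
                        config$eye_params$eye_center_offsets$left +
                        pose$translation)
    ecr <- as.numeric(pose$rotation %*%
                        config$eye_params$eye_center_offsets$right +
                        pose$translation)
    dir1 <- function(ec) {
      d <- tg - matrix(ec, length(times), 3, byrow = TRUE)
      d / sqrt(rowSums(d^2))
    }
    gl <- .jitter_dirs(dir1(ecl), config$angle_noise_deg, pose$rotation)
    gr <- .jitter_dirs(dir1(ecr), config$angle_noise_deg, pose$rotation)
    cyc_o <- (ecl + ecr) / 2
    cyc_d <- gl + gr
    cyc_d <- cyc_d / sqrt(rowSums(cyc_d^2))
    ang <- dirs_to_angles(cyc_d, pose$rotation)
    partner_pose <- config[[paste0("pose_", if (who == "p") "e" else "p")]]
    partner_metrics <- config[[paste0("metrics_",
                                      if (who == "p") "e" else "p")]]
    fp <- build_face_plane(partner_pose, partner_metrics)
    hit <- intersect_rays_plane(matrix(cyc_o, length(times), 3, byrow = TRUE),
                                cyc_d, fp$plane)
    isect <- to_plane_coords(fp$plane, hit$points)
    idx <- findInterval(times, sw)
    cond <- c("none", schedule$condition)[idx + 1]
    blink <- .blink_mask(times, config$blink_rate_hz, config$blink_mode)
    gt[[who]] <- data.frame(person_id = metrics$person_id,
                            timestamp = times, condition = cond,
                            gaze_az_deg = ang[, 1], gaze_el_deg = ang[, 2],
                            dir_x = cyc_d[, 1], dir_y = cyc_d[, 2],
                            dir_z = cyc_d[, 3],
                            target_x = tg[, 1], target_y = tg[, 2],
                            target_z = tg[, 3],
                            isect_x_cm = isect[, 1], isect_y_cm = isect[, 2],
                            blink = blink)
    person_state[[who]] <- list(pose = pose, metrics = metrics,
                                gl = gl, gr = gr, blink = blink)
  }

  obs_p <- obs_e <- NULL
  if (project) {
    obs_p <- .project_person(config$camera_p, config$pose_p,
                             config$metrics_p, config$eye_params, times,
                             person_state$p$gl, person_state$p$gr,
                             config$landmark_noise_px, config$pupil_noise_px,
                             person_state$p$blink, include_iris)
    obs_e <- .project_person(config$camera_e, config$pose_e,
                             config$metrics_e, config$eye_params, times,
                             person_state$e$gl, person_state$e$gr,
                             config$landmark_noise_px, config$pupil_noise_px,
                             person_state$e$blink, include_iris)
  }
  list(obs_p = obs_p, obs_e = obs_e,
       ground_truth = rbind(gt$p, gt$e), schedule = schedule, times = times)
}

#' Simulate a smooth-pursuit screen calibration session
#'
#' The participant tracks a smoothly moving nine-point target on a screen
#' plane facing them; optional spontaneous head movement adds a smooth,
#' bounded pose wander (within about 15 degrees of yaw/pitch).
#'
#' @param config a [scene_config()].
#' @param screen_distance_cm screen distance from the participant's face
#'   (default 70).
#' @param dwell_s,transition_s pursuit timing (see [nine_point_pursuit()]).
#' @param head_motion `"none"` or `"spontaneous"`.
#' @param include_iris forward-project iris ellipses.
#' @return list with `obs` (camera-side frame series), `screen` (the
#'   [plane3()]), `target_xy` (true in-plane target), `ground_truth`
#'   (per-frame true pose parameters, gaze directions and screen
#'   intersections) and `poses` (list of true [head_pose()] per frame).
#' @export
simulate_calibration_session <- function(config, screen_distance_cm = 70,
                                         dwell_s = 1.5, transition_s = 0.8,
                                         head_motion = c("none",
                                                         "spontaneous"),
                                         include_iris = TRUE) {
  head_motion <- match.arg(head_motion)
  set.seed(config$seed)
  rate <- config$frame_rate_hz
  total <- 9 * dwell_s + 8 * transition_s
  times <- seq(0, total - 1e-9, by = 1 / rate)
  n <- length(times)
  pose0 <- config$pose_p
  facing <- as.numeric(pose0$rotation[, 3])
  screen <- plane3(pose0$translation + facing * screen_distance_cm,
                   normal = -facing, basis_u = as.numeric(pose0$rotation[, 1]))
  tgt <- nine_point_pursuit(times, dwell_s = dwell_s,
                            transition_s = transition_s)
  tgt_world <- from_plane_coords(screen, cbind(tgt$x, tgt$y))

  poses <- vector("list", n)
  if (head_motion == "none") {
    for (i in seq_len(n)) poses[[i]] <- pose0
  } else {
    wander <- function() {
      raw <- stats::rnorm(n)
      k <- round(rate)                      # ~1 s moving-average smoothing
      sm <- stats::filter(raw, rep(1 / k, k), circular = TRUE)
      12 * pi / 180 * as.numeric(sm) / max(abs(sm), 1e-9)
    }
    yaw <- wander(); pitch <- wander()
    for (i in seq_len(n)) {
      R <- rodrigues(c(0, yaw[i], 0)) %*% rodrigues(c(pitch[i], 0, 0))
      poses[[i]] <- head_pose(pose0$rotation %*% R, pose0$translation,
                              timestamp = times[i])
    }
  }

  ep <- config$eye_params
  gl <- gr <- matrix(0, n, 3)
  ecl_all <- ecr_all <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ecl_all[i, ] <- as.numeric(poses[[i]]$rotation %*%
                                 ep$eye_center_offsets$left +
                                 poses[[i]]$translation)
    ecr_all[i, ] <- as.numeric(poses[[i]]$rotation %*%
                                 ep$eye_center_offsets$right +
                                 poses[[i]]$translation)
    gl[i, ] <- normalize(tgt_world[i, ] - ecl_all[i, ])
    gr[i, ] <- normalize(tgt_world[i, ] - ecr_all[i, ])
  }
  gl <- .jitter_dirs(gl, config$angle_noise_deg, pose0$rotation)
  gr <- .jitter_dirs(gr, config$angle_noise_deg, pose0$rotation)
  blink <- .blink_mask(times, config$blink_rate_hz, config$blink_mode)

  # observations: reuse the static-pose projector per frame when wandering
  if (head_motion == "none") {
    obs <- .project_person(config$camera_p, pose0, config$metrics_p, ep,
                           times, gl, gr, config$landmark_noise_px,
                           config$pupil_noise_px, blink, include_iris)
  } else {
    rows <- vector("list", n)
    for (i in seq_len(n))
      rows[[i]] <- .project_person(config$camera_p, poses[[i]],
                                   config$metrics_p, ep, times[i],
                                   gl[i, , drop = FALSE],
                                   gr[i, , drop = FALSE],
                                   config$landmark_noise_px,
                                   config$pupil_noise_px, blink[i],
                                   include_iris)
    obs <- do.call(rbind, rows)
  }
  cyc_d <- gl + gr
  cyc_d <- cyc_d / sqrt(rowSums(cyc_d^2))
  gt <- data.frame(person_id = config$metrics_p$person_id, timestamp = times,
                   target_x_cm = tgt$x, target_y_cm = tgt$y,
                   dir_x = cyc_d[, 1], dir_y = cyc_d[, 2], dir_z = cyc_d[, 3],
                   blink = blink)
  list(obs = obs, screen = screen, target_xy = cbind(tgt$x, tgt$y),
       ground_truth = gt, poses = poses, times = times,
       eye_centers = list(left = ecl_all, right = ecr_all),
       gaze_dirs = list(left = gl, right = gr),
       target_world = tgt_world)
}

#' Write a ground-truth table to CSV
#'
#' @param ground_truth the `ground_truth` data frame of a simulated session.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_ground_truth <- function(ground_truth, path) {
  utils::write.csv(ground_truth, path, row.names = FALSE)
  invisible(path)
}
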