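# End-to-end estimation pipeline: detector output -> exclusion -> Kalman
# smoothing -> head pose -> per-eye gaze -> cross-camera interpolation ->
# partner face-plane intersection -> affine calibration -> AOI labels.

PX_COLS <- c("left_eye_u", "left_eye_v", "right_eye_u", "right_eye_v",
             "mouth_u", "mouth_v", "nose_u", "nose_v",
             "pupil_left_u", "pupil_left_v", "pupil_right_u",
             "pupil_right_v")

#' Estimate one person's gaze stream from their camera's frame series
#'
#' Applies blink/outlier exclusion, constant-velocity Kalman filtering of
#' all pixel series, per-frame head-pose estimation (warm-started from the
#' previous frame) and two-sphere pupil-offset gaze estimation for both
#' eyes; the cyclopean gaze ray averages the two eyes.
#'
#' @param obs frame-series data frame (see [simulate_dyad_session()] /
#'   [read_frame_series()] for the column contract).
#' @param metrics the person's [face_metrics()].
#' @param camera the observing [camera_model()].
#' @param eye_params an [eye_model_params()] whose offsets are the
#'   calibrated eye rotation centers.
#' @param likelihood_threshold,confidence_threshold exclusion thresholds
#'   (see [exclude_frames()]).
#' @param measurement_noise_px Kalman measurement noise for the pixel
#'   series; 0 disables smoothing (noiseless input).
#' @param process_noise Kalman process noise.
#' @return list with `timestamps` (kept frames), `exclusion`
#'   ([exclude_frames()] report), `poses`, `landmarks_world` (n x 12:
#'   left/right eye, mouth, nose xyz), `origin` and `dir` (cyclopean ray,
#'   n x 3), per-eye `dir_left`/`dir_right`, `eye_valid`, and `angles`
#'   (n x 2 azimuth/elevation, degrees, relative to the person's facing).
#' @export
estimate_person_gaze <- function(obs, metrics, camera, eye_params,
                                 likelihood_threshold = 0.5,
                                 confidence_threshold = 0.5,
                                 measurement_noise_px = 0.5,
                                 process_noise = 200) {
  excl <- exclude_frames(obs, likelihood_threshold, confidence_threshold)
  kept <- excl$labels == "kept"
  if (sum(kept) < 2) stop("too few kept frames")
  ts <- obs$timestamp[kept]
  px <- as.matrix(obs[kept, PX_COLS])
  if (measurement_noise_px > 0)
    px <- kalman_smooth(ts, px, process_noise, measurement_noise_px)

  n <- length(ts)
  poses <- vector("list", n)
  lmw <- matrix(NA_real_, n, 12)
  ecl <- ecr <- matrix(NA_real_, n, 3)
  prev <- NULL
  lm_model <- landmark_matrix(metrics)
  for (i in seq_len(n)) {
    row <- list(timestamp = ts[i],
                landmark_px = list(left_eye = px[i, 1:2],
                                   right_eye = px[i, 3:4],
                                   mouth = px[i, 5:6], nose = px[i, 7:8]))
    pose <- estimate_head_pose(row, metrics, camera, init = prev)
    poses[[i]] <- pose
    prev <- pose
    pts <- lm_model %*% t(pose$rotation) +
      matrix(pose$translation, 4, 3, byrow = TRUE)
    lmw[i, ] <- as.numeric(t(pts))
    ecl[i, ] <- as.numeric(pose$rotation %*%
                             eye_params$eye_center_offsets$left +
                             pose$translation)
    ecr[i, ] <- as.numeric(pose$rotation %*%
                             eye_params$eye_center_offsets$right +
                             pose$translation)
  }
  gl <- gaze_dirs_from_pupils(camera, px[, 9:10, drop = FALSE], ecl,
                              eye_params$eyeball_radius)
  gr <- gaze_dirs_from_pupils(camera, px[, 11:12, drop = FALSE], ecr,
                              eye_params$eyeball_radius)
  eye_valid <- gl$valid & gr$valid
  cyc <- gl$dirs + gr$dirs
  cyc <- cyc / sqrt(rowSums(cyc^2))
  ref <- poses[[1]]$rotation
  list(timestamps = ts, exclusion = excl, poses = poses,
       landmarks_world = lmw, origin = (ecl + ecr) / 2, dir = cyc,
       dir_left = gl$dirs, dir_right = gr$dirs, eye_valid = eye_valid,
       angles = dirs_to_angles(cyc, ref))
}

#' Intersect one person's gaze with the partner's face plane
#'
#' The partner's posed 3D landmark series (estimated from the opposed
#' camera) is linearly interpolated to the gazer's timestamps; per frame a
#' face plane is fitted through the interpolated eyes and mouth and the
#' cyclopean gaze ray is intersected with it.
#'
#' @param gazer output of [estimate_person_gaze()] for the gazing person.
#' @param partner output of [estimate_person_gaze()] for the partner.
#' @param max_gap largest partner-series gap bridged by interpolation, s.
#' @return list with `isect_xy` (n x 2 in-plane cm, NA when invalid),
#'   `landmarks_2d` (n x 6: left_eye x,y, right_eye x,y, mouth x,y) and
#'   `valid`.
#' @export
intersect_partner_face <- function(gazer, partner, max_gap = 0.1) {
  al <- align_to_timestamps(partner$timestamps, partner$landmarks_world,
                            gazer$timestamps, max_gap = max_gap)
  n <- length(gazer$timestamps)
  isect <- matrix(NA_real_, n, 2)
  lm2 <- matrix(NA_real_, n, 6)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!al$valid[i] || !gazer$eye_valid[i]) next
    pts <- matrix(al$values[i, ], 4, 3, byrow = TRUE)
    rownames(pts) <- c("left_eye", "right_eye", "mouth", "nose")
    ctr <- colMeans(pts[1:3, ])
    fp <- tryCatch(face_plane_from_points(pts, facing = gazer$origin[i, ] - ctr),
                   error = function(e) NULL)
    if (is.null(fp)) next
    hit <- tryCatch(line_plane_intersection(
      ray3(gazer$origin[i, ], gazer$dir[i, ]), fp$plane),
      error = function(e) NULL)
    if (is.null(hit)) next
    isect[i, ] <- to_plane_coords(fp$plane, hit)
    lm2[i, ] <- as.numeric(t(fp$landmarks_2d[1:3, ]))
    valid[i] <- TRUE
  }
  list(isect_xy = isect, landmarks_2d = lm2, valid = valid)
}

#' Affine calibration from the first left/right/mouth fixation trials
#'
#' Coordinate-wise medians of the raw intersections over the last
#' `analysis_window_s` seconds of the first left-eye, right-eye and mouth
#' trials are mapped onto the median in-plane landmark positions of the
#' same windows.
#'
#' @param timestamps sample times, s.
#' @param isect_xy raw n x 2 in-plane intersections.
#' @param landmarks_2d n x 6 in-plane landmark series (as returned by
#'   [intersect_partner_face()]).
#' @param schedule a [trial_schedule()].
#' @param analysis_window_s window at the end of each calibration trial, s.
#' @return an [affine_calibration()].
#' @export
calibrate_from_first_trials <- function(timestamps, isect_xy, landmarks_2d,
                                        schedule, analysis_window_s = 4) {
  conds <- c("left_eye", "right_eye", "mouth")
  raw <- tgt <- matrix(NA_real_, 3, 2)
  for (k in seq_along(conds)) {
    i <- which(schedule$condition == conds[k])[1]
    if (is.na(i)) stop("schedule lacks a ", conds[k], " trial")
    t1 <- schedule$start_s[i] + schedule$duration_s[i]
    sel <- timestamps >= t1 - analysis_window_s & timestamps < t1 &
      stats::complete.cases(isect_xy)
    if (!any(sel)) stop("no valid samples in calibration trial ", i)
    raw[k, ] <- apply(isect_xy[sel, , drop = FALSE], 2, stats::median)
    lmcols <- (k - 1) * 2 + 1:2
    tgt[k, ] <- apply(landmarks_2d[sel, lmcols, drop = FALSE], 2,
                      stats::median)
  }
  fit_affine(raw, tgt)
}

# Vectorized per-frame AOI classification against a landmark series
# (n x 6); same rule as classify_aoi.
classify_aoi_series <- function(points, landmarks_2d, threshold_cm = 6.3) {
  aois <- c("left_eye", "right_eye", "mouth")
  d <- vapply(1:3, function(k)
    sqrt((points[, 1] - landmarks_2d[, (k - 1) * 2 + 1])^2 +
           (points[, 2] - landmarks_2d[, (k - 1) * 2 + 2])^2),
    numeric(nrow(points)))
  d <- matrix(d, nrow = nrow(points))
  nearest <- aois[max.col(-d, ties.method = "first")]
  lab <- ifelse(apply(d, 1, min) > threshold_cm, "outside", nearest)
  lab[!stats::complete.cases(points) | !stats::complete.cases(landmarks_2d)] <- NA
  factor(lab, levels = c(aois, "outside"))
}

#' Run the full dyad estimation pipeline on a simulated (or loaded) session
#'
#' For each person: gaze estimation from their camera, intersection with
#' the partner's face plane, optional affine calibration from the first
#' left/right/mouth trials, AOI classification, and per-condition
#' prediction rates over the last `analysis_window_s` seconds of each
#' trial.
#'
#' @param obs_p,obs_e frame-series data frames of the two cameras.
#' @param schedule the session's [trial_schedule()].
#' @param config the [scene_config()] (cameras, metrics, eye parameters).
#' @param calibrate apply the affine face-plane calibration (default TRUE).
#' @param threshold_cm AOI outside-threshold, cm.
#' @param analysis_window_s statistics window at the end of each trial, s.
#' @param measurement_noise_px Kalman measurement noise (0 = no smoothing).
#' @return list with per-person results `p` and `e`, each containing the
#'   [estimate_person_gaze()] output (`gaze`), `isect` (calibrated
#'   intersections + landmark series), `labels`, `rates`
#'   ([prediction_rates()]) and `calibration`.
#' @export
run_dyad_pipeline <- function(obs_p, obs_e, schedule, config,
                              calibrate = TRUE, threshold_cm = 6.3,
                              analysis_window_s = 4,
                              measurement_noise_px = 0.5) {
  est <- list(
    p = estimate_person_gaze(obs_p, config$metrics_p, config$camera_p,
                             config$eye_params,
                             measurement_noise_px = measurement_noise_px),
    e = estimate_person_gaze(obs_e, config$metrics_e, config$camera_e,
                             config$eye_params,
                             measurement_noise_px = measurement_noise_px))
  out <- list()
  for (who in c("p", "e")) {
    other <- if (who == "p") "e" else "p"
    ix <- intersect_partner_face(est[[who]], est[[other]])
    cal <- NULL
    xy <- ix$isect_xy
    if (calibrate) {
      cal <- calibrate_from_first_trials(est[[who]]$timestamps, ix$isect_xy,
                                         ix$landmarks_2d, schedule,
                                         analysis_window_s)
      ok <- stats::complete.cases(xy)
      xy[ok, ] <- apply_calibration(cal, xy[ok, , drop = FALSE])
    }
    labels <- classify_aoi_series(xy, ix$landmarks_2d, threshold_cm)
    rates <- prediction_rates(est[[who]]$timestamps, labels, schedule,
                              analysis_window_s,
                              exclude_calibration_trials = calibrate)
    out[[who]] <- list(gaze = est[[who]], isect = ix, calibrated_xy = xy,
                       labels = labels, rates = rates, calibration = cal)
  }
  out
}

#' Compare estimated gaze with simulator ground truth
#'
#' Matches kept frames to the ground-truth rows of the same person by
#' timestamp and reports the angular error between estimated and true
#' cyclopean gaze directions.
#'
#' @param est output of [estimate_person_gaze()].
#' @param ground_truth `ground_truth` data frame of the simulated session.
#' @param person_id person to compare against.
#' @return list with `median_error_deg`, `errors_deg` and `n`.
#' @export
gaze_error_vs_truth <- function(est, ground_truth, person_id) {
  gt <- ground_truth[ground_truth$person_id == person_id, ]
  idx <- match(round(est$timestamps, 6), round(gt$timestamp, 6))
  ok <- !is.na(idx) & est$eye_valid
  dirs_true <- as.matrix(gt[idx[ok], c("dir_x", "dir_y", "dir_z")])
  err <- angle_between_deg(est$dir[ok, , drop = FALSE], dirs_true)
  list(median_error_deg = stats::median(err), errors_deg = err,
       n = sum(ok))
}
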