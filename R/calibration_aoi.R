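# Screen-accuracy evaluation, affine face-plane calibration, nearest-
# landmark area-of-interest classification and per-condition rate tables.

#' Trial schedule of prompted gaze conditions
#'
#' @param conditions character vector of `left_eye`, `right_eye`, `mouth`,
#'   `outside`.
#' @param start_s trial onsets, s (ordered, non-overlapping).
#' @param duration_s trial durations, s (default 5).
#' @return data frame of class `trial_schedule` with columns `condition`,
#'   `start_s`, `duration_s`.
#' @export
trial_schedule <- function(conditions, start_s,
                           duration_s = rep(5, length(conditions))) {
  stopifnot(length(conditions) == length(start_s),
            all(conditions %in% c("left_eye", "right_eye", "mouth",
                                  "outside")))
  o <- order(start_s)
  conditions <- conditions[o]; start_s <- start_s[o]
  duration_s <- rep_len(duration_s, length(conditions))[o]
  if (any(diff(start_s) < duration_s[-length(start_s)] - 1e-9))
    stop("trials must not overlap")
  structure(data.frame(condition = conditions, start_s = start_s,
                       duration_s = duration_s),
            class = c("trial_schedule", "data.frame"))
}

#' Pseudo-random trial schedule
#'
#' Generates the prompted-condition protocol: `n_trials` trials of
#' `duration_s` seconds each, conditions drawn in pseudo-random order with
#' (near-)balanced counts.  Defaults match the 60 x 5 s protocol.
#'
#' @param n_trials number of trials (default 60).
#' @param duration_s trial length, s (default 5).
#' @param seed RNG seed.
#' @return a [trial_schedule()].
#' @export
make_trial_schedule <- function(n_trials = 60, duration_s = 5, seed = 1) {
  conds <- c("left_eye", "right_eye", "mouth", "outside")
  set.seed(seed)
  seq_cond <- sample(rep_len(conds, n_trials))
  # avoid starting with `outside`: the first left/right/mouth trials seed
  # the affine calibration, and an opening outside trial is uninformative
  first_face <- which(seq_cond != "outside")[1]
  if (first_face > 1) {
    tmp <- seq_cond[1]; seq_cond[1] <- seq_cond[first_face]
    seq_cond[first_face] <- tmp
  }
  trial_schedule(seq_cond, start_s = (seq_len(n_trials) - 1) * duration_s,
                 duration_s = rep(duration_s, n_trials))
}

#' Binocular point of regard on a screen plane
#'
#' Intersects the left- and right-eye gaze rays with the screen and averages
#' the two in-plane coordinates; if one ray is invalid the other is used.
#'
#' @param gaze_left,gaze_right [ray3()]s (either may be `NULL`/invalid).
#' @param screen a [plane3()].
#' @return length-2 in-plane (x, y) cm, or `NULL` when both rays fail.
#' @export
screen_gaze_point <- function(gaze_left, gaze_right, screen) {
  hit <- function(r) {
    if (is.null(r)) return(NULL)
    tryCatch(to_plane_coords(screen, line_plane_intersection(r, screen)),
             error = function(e) NULL)
  }
  pts <- Filter(Negate(is.null), list(hit(gaze_left), hit(gaze_right)))
  if (length(pts) == 0) return(NULL)
  colMeans(do.call(rbind, pts))
}

#' Accuracy / precision / robustness of an estimated gaze-point series
#'
#' Per-sample error is the visual angle of the Euclidean distance between
#' estimated and expected in-plane coordinates at the viewer distance.
#' Precision is the sample-to-sample RMS (RMS-S2S) of the estimated points
#' in degrees; robustness is the fraction of valid samples.
#'
#' @param estimated,expected n x 2 matrices of in-plane cm coordinates
#'   (NA rows in `estimated` count as invalid).
#' @param viewer_distance_cm distance from the viewer to the surface, cm.
#' @return object of class `accuracy_report`: `median_error_deg`,
#'   `errors_deg`, `precision_rms_s2s_deg`, `robustness`.
#' @export
angular_error_series <- function(estimated, expected, viewer_distance_cm) {
  stopifnot(nrow(estimated) == nrow(expected))
  ok <- stats::complete.cases(estimated)
  if (!any(ok)) stop("no valid overlapping samples")
  d <- sqrt(rowSums((estimated - expected)^2))
  err <- ifelse(ok, visual_angle(ifelse(ok, d, 0), viewer_distance_cm),
                NA_real_)
  both <- ok & c(FALSE, ok[-length(ok)])
  step <- sqrt(rowSums((estimated - rbind(NA, estimated[-nrow(estimated), ]))^2))
  prec <- sqrt(mean(visual_angle(step[both], viewer_distance_cm)^2))
  structure(list(median_error_deg = stats::median(err, na.rm = TRUE),
                 errors_deg = err,
                 precision_rms_s2s_deg = prec,
                 robustness = mean(ok)),
            class = "accuracy_report")
}

#' Smoothly moving nine-point pursuit target
#'
#' Visits all nine points of a 3x3 grid, dwelling `dwell_s` at each and
#' moving between consecutive points with a cosine-eased (continuous
#' velocity) transition of `transition_s`.  Total duration is
#' `9 * dwell_s + 8 * transition_s`.
#'
#' @param grid_half_width_cm,grid_half_height_cm half extents of the grid on
#'   the screen, cm.
#' @param dwell_s,transition_s segment durations, s.
#' @param times sample times, s (from 0).
#' @return data frame `t`, `x`, `y` of in-plane target coordinates.
#' @export
nine_point_pursuit <- function(times, grid_half_width_cm = 15,
                               grid_half_height_cm = 10,
                               dwell_s = 1.5, transition_s = 0.8) {
  gx <- c(-1, 0, 1) * grid_half_width_cm
  gy <- c(-1, 0, 1) * grid_half_height_cm
  order9 <- rbind(c(2, 2), c(1, 3), c(2, 3), c(3, 3), c(3, 2),
                  c(3, 1), c(2, 1), c(1, 1), c(1, 2))
  pts <- cbind(gx[order9[, 1]], gy[order9[, 2]])
  pos1 <- function(t) {
    seg <- dwell_s + transition_s
    if (t >= 8 * seg + dwell_s) return(pts[9, ])
    i <- floor(t / seg) + 1                      # current dwell index
    tt <- t - (i - 1) * seg
    if (tt <= dwell_s || i >= 9) return(pts[i, ])
    w <- (1 - cos(pi * (tt - dwell_s) / transition_s)) / 2
    (1 - w) * pts[i, ] + w * pts[i + 1, ]
  }
  xy <- t(vapply(pmax(times, 0), pos1, numeric(2)))
  data.frame(t = times, x = xy[, 1], y = xy[, 2])
}

#' Affine face-plane calibration from three landmark fixations
#'
#' Solves the exact 2D affine map sending three (non-collinear) raw median
#' gaze points to the corresponding facial-landmark coordinates.
#'
#' @param raw_medians 3 x 2 matrix of uncalibrated in-plane medians
#'   (left eye, right eye, mouth fixation trials).
#' @param targets 3 x 2 matrix of the landmark in-plane coordinates.
#' @return object of class `affine_calibration` with `matrix` (2x2) and
#'   `offset` (length 2, cm).  Signals `dyadgaze_degenerate_calibration`
#'   for collinear inputs.
#' @export
fit_affine <- function(raw_medians, targets) {
  stopifnot(all(dim(raw_medians) == c(3, 2)), all(dim(targets) == c(3, 2)))
  area2 <- abs((raw_medians[2, 1] - raw_medians[1, 1]) *
                 (raw_medians[3, 2] - raw_medians[1, 2]) -
               (raw_medians[3, 1] - raw_medians[1, 1]) *
                 (raw_medians[2, 2] - raw_medians[1, 2]))
  if (area2 < 1e-10)
    stop(structure(class = c("dyadgaze_degenerate_calibration", "error",
                             "condition"),
                   list(message = "collinear calibration points",
                        call = sys.call())))
  X <- cbind(raw_medians, 1)
  sol <- solve(X, targets)               # rows: m11 m21 | m12 m22 | b
  M <- t(sol[1:2, ])
  affine_calibration(M, as.numeric(sol[3, ]))
}

#' @rdname fit_affine
#' @param matrix 2x2 linear part (must be invertible).
#' @param offset length-2 translation, cm.
#' @export
affine_calibration <- function(matrix = diag(2), offset = c(0, 0)) {
  stopifnot(all(dim(matrix) == c(2, 2)))
  if (abs(det(matrix)) <= 1e-10) stop("calibration matrix must be invertible")
  structure(list(matrix = matrix, offset = as.numeric(offset)),
            class = "affine_calibration")
}

#' Apply (or invert) an affine calibration
#'
#' @param cal an [affine_calibration()].
#' @param points length-2 vector or n x 2 matrix of in-plane coordinates.
#' @param inverse apply the inverse map instead.
#' @return transformed coordinates, same shape as `points`.
#' @export
apply_calibration <- function(cal, points, inverse = FALSE) {
  p <- if (is.matrix(points)) points else matrix(points, 1)
  out <- if (inverse) {
    (p - matrix(cal$offset, nrow(p), 2, byrow = TRUE)) %*% t(solve(cal$matrix))
  } else {
    p %*% t(cal$matrix) + matrix(cal$offset, nrow(p), 2, byrow = TRUE)
  }
  if (is.matrix(points)) out else as.numeric(out)
}

#' Classify in-plane gaze points into facial areas of interest
#'
#' A point farther than `threshold_cm` from every facial landmark (left eye,
#' right eye, mouth) is `outside`; otherwise it takes the label of the
#' nearest landmark.  The default threshold, 6.3 cm, corresponds to about 3
#' degrees of visual angle at a 120 cm interpersonal distance.
#'
#' @param points length-2 vector or n x 2 matrix of calibrated in-plane cm
#'   coordinates.
#' @param landmarks_2d matrix with rows named `left_eye`, `right_eye`,
#'   `mouth` (a `face_plane$landmarks_2d` works; extra rows ignored).
#' @param threshold_cm outside threshold, cm (default 6.3).
#' @return factor of labels `left_eye`, `right_eye`, `mouth`, `outside`
#'   (NA input rows give NA).
#' @export
classify_aoi <- function(points, landmarks_2d, threshold_cm = 6.3) {
  p <- if (is.matrix(points)) points else matrix(points, 1)
  aois <- c("left_eye", "right_eye", "mouth")
  lm <- landmarks_2d[aois, , drop = FALSE]
  d <- vapply(aois, function(k)
    sqrt((p[, 1] - lm[k, 1])^2 + (p[, 2] - lm[k, 2])^2), numeric(nrow(p)))
  d <- matrix(d, nrow = nrow(p))
  nearest <- aois[max.col(-d, ties.method = "first")]
  lab <- ifelse(apply(d, 1, min) > threshold_cm, "outside", nearest)
  lab[!stats::complete.cases(p)] <- NA
  factor(lab, levels = c(aois, "outside"))
}

#' Per-condition AOI prediction-rate table
#'
#' For every trial (optionally excluding the first left-eye, right-eye and
#' mouth trials, which seed the affine calibration) the fraction of kept
#' samples in the analysis window (the last `analysis_window_s` seconds of
#' the trial) classified into each label is computed; per-condition rates
#' are medians across trials.  The correct-classification rate is the
#' diagonal of the table.
#'
#' @param timestamps sample times, s.
#' @param labels factor of AOI labels per sample (NA = excluded sample).
#' @param schedule a [trial_schedule()].
#' @param analysis_window_s seconds at the end of each trial to analyze
#'   (default 4).
#' @param exclude_calibration_trials drop the first left/right/mouth trials
#'   (default TRUE).
#' @return object of class `prediction_rates`: `table` (condition x label
#'   median rates), `per_trial` data frame, `median_correct` (median of the
#'   diagonal entries over conditions present), `skipped_trials`.
#' @export
prediction_rates <- function(timestamps, labels, schedule,
                             analysis_window_s = 4,
                             exclude_calibration_trials = TRUE) {
  lv <- c("left_eye", "right_eye", "mouth", "outside")
  drop_idx <- integer(0)
  if (exclude_calibration_trials)
    drop_idx <- vapply(c("left_eye", "right_eye", "mouth"),
                       function(k) which(schedule$condition == k)[1],
                       integer(1))
  per <- list(); skipped <- integer(0)
  for (i in seq_len(nrow(schedule))) {
    if (i %in% drop_idx) next
    t1 <- schedule$start_s[i] + schedule$duration_s[i]
    sel <- timestamps >= t1 - analysis_window_s & timestamps < t1 &
      !is.na(labels)
    if (!any(sel)) { skipped <- c(skipped, i); next }
    tab <- table(factor(labels[sel], levels = lv))
    per[[length(per) + 1]] <-
      data.frame(trial = i, condition = schedule$condition[i],
                 t(as.numeric(tab / sum(tab))))
  }
  if (length(per) == 0) stop("no trials with kept samples")
  per <- do.call(rbind, per)
  names(per)[3:6] <- lv
  tabm <- t(vapply(lv, function(cond) {
    rows <- per[per$condition == cond, lv, drop = FALSE]
    if (nrow(rows) == 0) rep(NA_real_, 4) else apply(rows, 2, stats::median)
  }, numeric(4)))
  dimnames(tabm) <- list(condition = lv, label = lv)
  structure(list(table = tabm, per_trial = per,
                 median_correct = stats::median(diag(tabm), na.rm = TRUE),
                 skipped_trials = skipped),
            class = "prediction_rates")
}

#' Friedman rank test across conditions
#'
#' Nonparametric repeated-measures test on an n-participants by k-conditions
#' rate matrix (average ranks for ties; chi-square approximation with
#' k - 1 degrees of freedom).
#'
#' @param rates n x k numeric matrix.
#' @return list with `Q` (statistic), `df`, `p`, `n`.
#' @export
friedman_rates_test <- function(rates) {
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) >= 2, ncol(rates) >= 2)
  if (all(apply(rates, 1, function(r) max(r) == min(r))))
    return(list(Q = 0, df = ncol(rates) - 1, p = 1, n = nrow(rates)))
  ft <- stats::friedman.test(rates)
  list(Q = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, n = nrow(rates))
}
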