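# Interpersonal gaze-movement synchrony: windowed time-lagged
# cross-correlation of two persons' gaze-angle series (azimuth/elevation of
# the cyclopean gaze direction, head + eye movement combined), contrasting
# same-trial window pairs against null pairs offset by 5 s.

#' Gaze-angle time series for one person
#'
#' @param person_id label.
#' @param timestamps increasing sample times, s.
#' @param azimuth,elevation gaze angles in degrees (world frame, relative
#'   to the person's nominal facing direction).
#' @param valid logical per sample (default all TRUE).
#' @return object of class `gaze_angle_series`.
#' @export
gaze_angle_series <- function(person_id, timestamps, azimuth, elevation,
                              valid = rep(TRUE, length(timestamps))) {
  stopifnot(length(azimuth) == length(timestamps),
            length(elevation) == length(timestamps))
  if (any(diff(timestamps) <= 0)) stop("timestamps must increase")
  structure(list(person_id = person_id, timestamps = as.numeric(timestamps),
                 azimuth = as.numeric(azimuth),
                 elevation = as.numeric(elevation),
                 valid = valid & is.finite(azimuth) & is.finite(elevation)),
            class = "gaze_angle_series")
}

#' Convert gaze direction vectors to azimuth/elevation degrees
#'
#' Azimuth is the signed angle of the direction's projection onto the
#' reference x-z plane, elevation the angle above it, both relative to a
#' reference frame (columns x, y, z; z the nominal facing direction).
#'
#' @param dirs n x 3 matrix of (not necessarily unit) world directions.
#' @param ref 3x3 reference rotation (default identity).
#' @return n x 2 matrix `azimuth`, `elevation` in degrees.
#' @export
dirs_to_angles <- function(dirs, ref = diag(3)) {
  d <- dirs %*% ref                       # components in reference axes
  cbind(azimuth = atan2(d[, 1], d[, 3]) * 180 / pi,
        elevation = atan2(d[, 2], sqrt(d[, 1]^2 + d[, 3]^2)) * 180 / pi)
}

# Resample a gaze_angle_series onto a uniform grid [t0, t1) at `rate` Hz.
resample_angles <- function(series, t0, t1, rate = 30, max_gap = 0.1) {
  grid <- seq(t0, t1 - 1e-9, by = 1 / rate)
  ok <- series$valid
  if (sum(ok) < 2) return(list(t = grid,
                               az = rep(NA_real_, length(grid)),
                               el = rep(NA_real_, length(grid))))
  al <- align_to_timestamps(series$timestamps[ok],
                            cbind(series$azimuth[ok], series$elevation[ok]),
                            grid, max_gap = max_gap)
  list(t = grid, az = al$values[, 1], el = al$values[, 2])
}

#' Time-lagged cross-correlation of two gaze-angle windows
#'
#' Both windows must already lie on a common uniform grid (same sampling
#' step).  For every lag on the step grid up to `max_lag_s`, the Pearson
#' correlation of the overlapping segments is computed per channel
#' (azimuth, elevation) and averaged; the maximum over lags and the
#' absolute lag where it occurs are returned.
#'
#' @param a,b lists with equal-length numeric `az`, `el` (uniform grid).
#' @param step_s grid step, s (default 1/30).
#' @param max_lag_s largest |lag| examined, s (default 1.5).
#' @param min_overlap smallest admissible overlap per lag (default 10).
#' @return list with `lags` (s), `correlations`, `max_correlation`,
#'   `lag_at_max_s` (absolute value), `ok` (FALSE when every lag was
#'   undefined, e.g. constant input).
#' @export
lagged_crosscorr <- function(a, b, step_s = 1 / 30, max_lag_s = 1.5,
                             min_overlap = 10) {
  n <- length(a$az)
  stopifnot(length(b$az) == n, length(a$el) == n, length(b$el) == n)
  K <- floor(max_lag_s / step_s + 1e-9)
  lags <- (-K):K
  cors <- vapply(lags, function(k) {
    ia <- if (k >= 0) seq_len(n - k) else (1 - k):n    # b shifted by +k steps
    ib <- ia + k
    keep <- is.finite(a$az[ia]) & is.finite(b$az[ib]) &
      is.finite(a$el[ia]) & is.finite(b$el[ib])
    if (sum(keep) < min_overlap) return(NA_real_)
    ia <- ia[keep]; ib <- ib[keep]
    mean(c(.pearson_or_na(a$az[ia], b$az[ib]),
           .pearson_or_na(a$el[ia], b$el[ib])), na.rm = TRUE)
  }, numeric(1))
  if (all(!is.finite(cors)))
    return(list(lags = lags * step_s, correlations = cors,
                max_correlation = NA_real_, lag_at_max_s = NA_real_,
                ok = FALSE))
  i <- which.max(cors)
  list(lags = lags * step_s, correlations = cors,
       max_correlation = cors[i], lag_at_max_s = abs(lags[i]) * step_s,
       ok = TRUE)
}

.pearson_or_na <- function(x, y) {
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
  stats::cor(x, y)
}

#' Build synchronized and null window pairs from a trial schedule
#'
#' For each trial, the synchronized pair is both persons' first
#' `window_s` seconds of that trial; the null ("unsynchronized") pair takes
#' the partner window starting `null_offset_s` later.  Pairs lacking enough
#' valid samples, or whose null window runs past the end of the data, are
#' dropped.
#'
#' @param series_p,series_e [gaze_angle_series()] of the two persons.
#' @param schedule a [trial_schedule()].
#' @param window_s window length, s (default 2).
#' @param null_offset_s offset of the null partner window, s (default 5).
#' @param rate resampling rate, Hz (default 30).
#' @return list of elements with `window_id`, `sync` (list a, b) and
#'   `unsync` (list a, b), each window a uniform-grid `az`/`el` list.
#' @export
build_window_pairs <- function(series_p, series_e, schedule, window_s = 2,
                               null_offset_s = 5, rate = 30) {
  t_end <- min(max(series_p$timestamps), max(series_e$timestamps))
  out <- list()
  usable <- function(w) mean(is.finite(w$az)) >= 0.5
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$start_s[i]
    if (t0 + null_offset_s + window_s > t_end + 1e-9) next
    wp <- resample_angles(series_p, t0, t0 + window_s, rate)
    we <- resample_angles(series_e, t0, t0 + window_s, rate)
    wu <- resample_angles(series_e, t0 + null_offset_s,
                          t0 + null_offset_s + window_s, rate)
    if (!usable(wp) || !usable(we) || !usable(wu)) next
    out[[length(out) + 1]] <- list(window_id = i,
                                   sync = list(a = wp, b = we),
                                   unsync = list(a = wp, b = wu))
  }
  out
}

#' Synchrony results for one participant's windows
#'
#' Runs [lagged_crosscorr()] on every synchronized and null pair.
#'
#' @param pairs output of [build_window_pairs()].
#' @param ... passed to [lagged_crosscorr()].
#' @return data frame with `window_id`, `synchronized`, `max_correlation`,
#'   `lag_at_max_s` (undefined windows dropped).
#' @export
synchrony_windows <- function(pairs, ...) {
  rows <- list()
  for (p in pairs) {
    for (flag in c(TRUE, FALSE)) {
      w <- if (flag) p$sync else p$unsync
      r <- lagged_crosscorr(w$a, w$b, ...)
      if (!r$ok) next
      rows[[length(rows) + 1]] <-
        data.frame(window_id = p$window_id, synchronized = flag,
                   max_correlation = r$max_correlation,
                   lag_at_max_s = r$lag_at_max_s)
    }
  }
  if (length(rows) == 0) return(data.frame(window_id = integer(0),
                                           synchronized = logical(0),
                                           max_correlation = numeric(0),
                                           lag_at_max_s = numeric(0)))
  do.call(rbind, rows)
}

#' Per-participant medians of windowed synchrony results
#'
#' @param results data frame as returned by [synchrony_windows()].
#' @return list with `median_correlation_sync`, `median_correlation_unsync`,
#'   `median_lag_sync`, `median_lag_unsync` and `complete` (FALSE when a
#'   condition has no windows).
#' @export
summarize_per_participant <- function(results) {
  med <- function(flag, col) {
    v <- results[results$synchronized == flag, col]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }
  out <- list(median_correlation_sync = med(TRUE, "max_correlation"),
              median_correlation_unsync = med(FALSE, "max_correlation"),
              median_lag_sync = med(TRUE, "lag_at_max_s"),
              median_lag_unsync = med(FALSE, "lag_at_max_s"))
  out$complete <- all(vapply(out[1:4], is.finite, TRUE))
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' W is the smaller of the positive and negative rank sums (ties receive
#' average ranks; zero differences are dropped).  The default p-value uses
#' the normal approximation without continuity correction,
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)`; `mode = "exact"` uses the
#' exact signed-rank distribution instead.
#'
#' @param x,y paired samples, or differences in `x` with `y = NULL`.
#' @param mode `"normal"` (default) or `"exact"`.
#' @return list with `W`, `n` (nonzero pairs), `z` (normal mode) and
#'   `p` (two-sided).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0 & is.finite(d)]
  n <- length(d)
  if (n == 0) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  Wpos <- sum(r[d > 0])
  W <- min(Wpos, n * (n + 1) / 2 - Wpos)
  if (mode == "normal") {
    if (n < 5) warning("normal approximation unreliable for n < 5")
    z <- (W - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p <- min(1, 2 * stats::pnorm(z))
    list(W = W, n = n, z = z, p = p)
  } else {
    p <- min(1, 2 * stats::psignrank(W, n))
    list(W = W, n = n, z = NA_real_, p = p)
  }
}

#' Group-level synchrony report
#'
#' Aggregates per-participant medians and runs paired Wilcoxon signed-rank
#' tests contrasting synchronized against null windows on the maximum
#' correlation and on the absolute lag.
#'
#' @param per_participant data frame with one row per participant and
#'   columns `median_correlation_sync`, `median_correlation_unsync`,
#'   `median_lag_sync`, `median_lag_unsync`.
#' @param mode p-value mode for [wilcoxon_signed_rank()].
#' @return list with group medians, `test_correlation`, `test_lag` and
#'   `underpowered` (TRUE for fewer than 5 participants).
#' @export
synchrony_report <- function(per_participant, mode = "normal") {
  if (nrow(per_participant) == 0) stop("no participants")
  med <- function(col) stats::median(per_participant[[col]], na.rm = TRUE)
  res <- list(n_participants = nrow(per_participant),
              median_correlation_sync = med("median_correlation_sync"),
              median_correlation_unsync = med("median_correlation_unsync"),
              median_lag_sync = med("median_lag_sync"),
              median_lag_unsync = med("median_lag_unsync"),
              underpowered = nrow(per_participant) < 5)
  res$test_correlation <- wilcoxon_signed_rank(
    per_participant$median_correlation_sync,
    per_participant$median_correlation_unsync, mode = mode)
  res$test_lag <- wilcoxon_signed_rank(
    per_participant$median_lag_sync,
    per_participant$median_lag_unsync, mode = mode)
  res
}
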