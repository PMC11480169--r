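# Smoothing and screening of detector output streams: constant-velocity
# Kalman filtering per coordinate, blink/outlier exclusion by likelihood
# thresholds, and linear cross-camera temporal alignment.

#' Constant-velocity Kalman filter for a timestamped point series
#'
#' Each coordinate is filtered independently with a two-state
#' (position, velocity) model driven by white acceleration noise; variable
#' frame intervals are handled exactly.  With `measurement_noise = 0` the
#' filter reduces to the identity.
#'
#' @param timestamps strictly increasing times, s.
#' @param values numeric vector or n x d matrix of measurements.
#' @param process_noise white-acceleration spectral density, (units/s^2)^2
#'   per Hz; default 1.
#' @param measurement_noise measurement standard deviation, same units as
#'   `values`.
#' @return filtered values, same shape as `values`.
#' @export
kalman_smooth <- function(timestamps, values, process_noise = 1,
                          measurement_noise = 1) {
  if (length(timestamps) < 2) stop("need at least 2 samples")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  stopifnot(nrow(v) == length(timestamps))
  out <- v
  Rm <- measurement_noise^2
  for (j in seq_len(ncol(v))) {
    x <- c(v[1, j], 0)                      # state: position, velocity
    P <- diag(c(Rm, 100))
    out[1, j] <- x[1]
    for (i in 2:nrow(v)) {
      dt <- timestamps[i] - timestamps[i - 1]
      FF <- matrix(c(1, 0, dt, 1), 2, 2)
      Q <- process_noise * matrix(c(dt^4 / 4, dt^3 / 2,
                                    dt^3 / 2, dt^2), 2, 2)
      x <- FF %*% x
      P <- FF %*% P %*% t(FF) + Q
      S <- P[1, 1] + Rm
      K <- P[, 1] / S
      x <- x + K * (v[i, j] - x[1])
      P <- (diag(2) - K %*% t(c(1, 0))) %*% P
      out[i, j] <- x[1]
    }
  }
  if (is.matrix(values)) out else as.numeric(out)
}

#' Exclusion report
#'
#' Labels every frame as `kept`, `blink` (either eye's open-likelihood
#' strictly below the likelihood threshold) or `outlier` (detection
#' confidence strictly below the confidence threshold); blinks take
#' precedence.  A value exactly at a threshold is kept.
#'
#' @param obs frame-series data frame with columns
#'   `eye_open_likelihood_left`, `eye_open_likelihood_right`,
#'   `detection_confidence`.
#' @param likelihood_threshold,confidence_threshold in `[0, 1]`
#'   (defaults 0.5).
#' @return object of class `exclusion_report`: `n_total`, `n_blink`,
#'   `n_outlier`, `fraction_excluded`, `labels` (factor per frame).
#' @export
exclude_frames <- function(obs, likelihood_threshold = 0.5,
                           confidence_threshold = 0.5) {
  stopifnot(likelihood_threshold >= 0, likelihood_threshold <= 1,
            confidence_threshold >= 0, confidence_threshold <= 1)
  lik <- pmin(obs$eye_open_likelihood_left, obs$eye_open_likelihood_right)
  blink <- lik < likelihood_threshold
  outlier <- !blink & obs$detection_confidence < confidence_threshold
  labels <- factor(ifelse(blink, "blink", ifelse(outlier, "outlier", "kept")),
                   levels = c("kept", "blink", "outlier"))
  n <- length(labels)
  structure(list(n_total = n, n_blink = sum(blink), n_outlier = sum(outlier),
                 fraction_excluded = (sum(blink) + sum(outlier)) / n,
                 labels = labels),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d frames, %d blink, %d outlier (%.2f%% excluded)\n",
              x$n_total, x$n_blink, x$n_outlier, 100 * x$fraction_excluded))
  invisible(x)
}

#' Linearly interpolate a series onto another camera's timestamps
#'
#' Samples that would require extrapolation, or that fall inside a source
#' gap longer than `max_gap`, are marked invalid (NA).
#'
#' @param timestamps_a increasing source timestamps, s.
#' @param values_a numeric vector or n x d matrix of source values.
#' @param timestamps_b target timestamps, s.
#' @param max_gap largest source gap (s) a target sample may bridge
#'   (default 0.1).
#' @return list with `values` (same width as `values_a`, NA where invalid)
#'   and `valid` (logical per target sample).
#' @export
align_to_timestamps <- function(timestamps_a, values_a, timestamps_b,
                                max_gap = 0.1) {
  if (length(timestamps_a) == 0) stop("empty source series")
  if (any(diff(timestamps_a) <= 0)) stop("source timestamps must increase")
  va <- if (is.matrix(values_a)) values_a else matrix(values_a, ncol = 1)
  idx <- findInterval(timestamps_b, timestamps_a)
  inside <- idx >= 1 & idx < length(timestamps_a)
  at_end <- timestamps_b == timestamps_a[length(timestamps_a)]
  gap_ok <- rep(FALSE, length(timestamps_b))
  gap_ok[inside] <- (timestamps_a[idx[inside] + 1] -
                       timestamps_a[idx[inside]]) <= max_gap
  valid <- (inside & gap_ok) | at_end
  out <- matrix(NA_real_, length(timestamps_b), ncol(va))
  if (any(valid)) {
    for (j in seq_len(ncol(va)))
      out[valid, j] <- stats::approx(timestamps_a, va[, j],
                                     xout = timestamps_b[valid])$y
  }
  list(values = if (is.matrix(values_a)) out else as.numeric(out),
       valid = valid)
}
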