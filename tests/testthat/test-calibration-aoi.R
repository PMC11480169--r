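test_that("binocular screen gaze averages the in-plane intersections", {
  screen <- plane3(c(0, 0, 0), c(0, 0, -1), basis_u = c(1, 0, 0))
  r <- ray3(c(0, 0, -70), c(0.1, 0.05, 1))
  expect_equal(screen_gaze_point(r, r, screen),
               to_plane_coords(screen, line_plane_intersection(r, screen)),
               tolerance = 1e-12)
  # symmetric rays about the normal -> midpoint
  rl <- ray3(c(-3, 0, -70), c(3 / 70, 0, 1))
  rr <- ray3(c(3, 0, -70), c(-3 / 70, 0, 1))
  expect_equal(screen_gaze_point(rl, rr, screen), c(0, 0), tolerance = 1e-9)
  # one invalid ray: the other is used; both invalid: NULL
  par <- ray3(c(0, 0, -70), c(1, 0, 0))
  expect_equal(screen_gaze_point(par, r, screen),
               screen_gaze_point(r, r, screen), tolerance = 1e-12)
  expect_null(screen_gaze_point(par, par, screen))
})

test_that("simulated screen fixations are recovered within 0.01 cm", {
  cfg <- scene_config(seed = 4)
  ses <- simulate_calibration_session(cfg, include_iris = FALSE)
  idx <- round(seq(1, length(ses$times), length.out = 20))
  for (i in idx) {
    gl <- ray3(ses$eye_centers$left[i, ], ses$gaze_dirs$left[i, ])
    gr <- ray3(ses$eye_centers$right[i, ], ses$gaze_dirs$right[i, ])
    got <- screen_gaze_point(gl, gr, ses$screen)
    expect_lt(dyadgaze:::vnorm(got - ses$target_xy[i, ]), 0.01)
  }
})

test_that("angular error series reports the inverse-tangent conversion and robustness", {
  est <- matrix(c(0, 0), 10, 2, byrow = TRUE)
  rep0 <- angular_error_series(est, est, 70)
  expect_equal(rep0$median_error_deg, 0)
  expect_equal(rep0$robustness, 1)
  # a constant 2.56 cm offset at 71.9 cm is 2.04 degrees of visual angle
  off <- est; off[, 1] <- off[, 1] + 2.56
  rep1 <- angular_error_series(off, est, 71.9)
  expect_equal(rep1$median_error_deg, atan(2.56 / 71.9) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(round(rep1$median_error_deg, 2), 2.04)
  # NA rows lower robustness
  off[3, ] <- NA
  expect_equal(angular_error_series(off, est, 71.9)$robustness, 0.9)
})

test_that("median angular error under Gaussian noise matches a Monte-Carlo oracle", {
  set.seed(71)
  sigma <- 1.5; d <- 70; n <- 4000
  est <- cbind(rnorm(n, 0, sigma), rnorm(n, 0, sigma))
  rep_ <- angular_error_series(est, matrix(0, n, 2), d)
  # oracle: median of the Rayleigh offset distribution, converted to degrees
  oracle <- atan(sigma * sqrt(2 * log(2)) / d) * 180 / pi
  expect_equal(rep_$median_error_deg, oracle, tolerance = 0.05 * oracle)
})

test_that("nine-point pursuit visits every grid point continuously with the scheduled duration", {
  dwell <- 1.2; trans <- 0.6
  total <- 9 * dwell + 8 * trans
  ts <- seq(0, total, by = 0.005)
  tr <- nine_point_pursuit(ts, 15, 10, dwell, trans)
  pts <- unique(tr[, c("x", "y")])
  for (gx in c(-15, 0, 15)) for (gy in c(-10, 0, 10))
    expect_true(any(abs(pts$x - gx) < 1e-9 & abs(pts$y - gy) < 1e-9))
  # continuous position: no jump exceeds max speed * dt
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  vmax <- pi * sqrt(30^2 + 20^2) / (2 * trans)   # cosine-easing peak speed
  expect_lt(max(step), vmax * 0.005 * 1.01)
  # after the final dwell the target stays put
  tail_xy <- nine_point_pursuit(c(total, total + 5), 15, 10, dwell, trans)
  expect_equal(tail_xy$x[1], tail_xy$x[2])
})

test_that("affine calibration solves exact correspondences and inverts random affines", {
  tri <- rbind(c(0, 0), c(4, 1), c(1, 5))
  id <- fit_affine(tri, tri)
  expect_equal(id$matrix, diag(2), tolerance = 1e-9)
  expect_equal(id$offset, c(0, 0), tolerance = 1e-9)
  sh <- fit_affine(tri + matrix(c(1, 2), 3, 2, byrow = TRUE), tri)
  expect_equal(sh$matrix, diag(2), tolerance = 1e-9)
  expect_equal(sh$offset, c(-1, -2), tolerance = 1e-9)
  set.seed(81)
  for (i in 1:100) {
    A <- matrix(rnorm(4), 2, 2)
    if (abs(det(A)) < 0.05) next
    b <- rnorm(2)
    raw <- tri %*% t(A) + matrix(b, 3, 2, byrow = TRUE)
    cal <- fit_affine(raw, tri)
    expect_equal(cal$matrix, solve(A), tolerance = 1e-9)
    pts <- matrix(rnorm(20), 10, 2)
    expect_equal(apply_calibration(cal, pts %*% t(A) +
                                     matrix(b, 10, 2, byrow = TRUE)),
                 pts, tolerance = 1e-7)
    expect_equal(apply_calibration(cal, apply_calibration(cal, pts),
                                   inverse = TRUE), pts, tolerance = 1e-9)
  }
  expect_error(fit_affine(rbind(c(0, 0), c(1, 1), c(2, 2)), tri),
               class = "dyadgaze_degenerate_calibration")
})

test_that("AOI classification follows the nearest-landmark rule with a 6.3 cm outside threshold", {
  lm <- rbind(left_eye = c(-3.1, 0), right_eye = c(3.1, 0),
              mouth = c(0, -7.2))
  expect_equal(as.character(classify_aoi(c(0, -7.2), lm)), "mouth")
  expect_equal(as.character(classify_aoi(c(-2.9, 0.3), lm)), "left_eye")
  # distances (7, 8, 9)-ish: everything beyond 6.3 cm is outside
  far <- c(-3.1 - 7, 0)
  expect_equal(as.character(classify_aoi(far, lm)), "outside")
  expect_equal(as.character(classify_aoi(c(-3.1 - 6.29, 0), lm)), "left_eye")
  # threshold consistency: 3 degrees at 120 cm converts to ~6.3 cm
  expect_equal(offset_from_angle(3, 120), 6.3, tolerance = 0.02)
  expect_true(is.na(classify_aoi(c(NA, 1), lm)))
})

test_that("prediction-rate rows are distributions and perfect labels give a perfect diagonal", {
  sched <- trial_schedule(rep(c("left_eye", "right_eye", "mouth", "outside"),
                              3), (0:11) * 5)
  ts <- seq(0, 60 - 1 / 30, by = 1 / 30)
  cond <- as.character(sched$condition[findInterval(ts, sched$start_s)])
  labels <- factor(cond, levels = c("left_eye", "right_eye", "mouth",
                                    "outside"))
  pr <- prediction_rates(ts, labels, sched)
  expect_equal(unname(diag(pr$table)), rep(1, 4))
  expect_equal(pr$median_correct, 1)
  expect_equal(unname(rowSums(pr$table)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(rowSums(pr$per_trial[, 3:6]) - 1 < 1e-12))
  # calibration trials excluded: first left/right/mouth trials absent
  expect_false(any(pr$per_trial$trial %in% c(1, 2, 3)))
  # masked samples skip the trial
  labels2 <- labels; labels2[ts >= 55] <- NA
  pr2 <- prediction_rates(ts, labels2, sched)
  expect_equal(pr2$skipped_trials, 12L)
})

test_that("Friedman test matches the hand-ranked statistic and degenerates to Q = 0", {
  same <- matrix(5, 4, 3)
  res <- friedman_rates_test(same)
  expect_equal(res$Q, 0)
  expect_equal(res$p, 1)
  # 4 x 3 toy matrix, no ties: Q = 12/(nk(k+1)) sum Rj^2 - 3n(k+1)
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 1, 2), c(5, 6, 4))
  ranks <- t(apply(m, 1, rank))
  Rj <- colSums(ranks)
  n <- 4; k <- 3
  Q_hand <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  res2 <- friedman_rates_test(m)
  expect_equal(res2$Q, Q_hand, tolerance = 1e-12)
  expect_equal(res2$df, k - 1)
  expect_equal(res2$p, stats::pchisq(Q_hand, k - 1, lower.tail = FALSE),
               tolerance = 1e-12)
})
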