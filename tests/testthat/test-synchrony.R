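mk_win <- function(az, el = az) list(az = az, el = el)

test_that("lagged cross-correlation peaks at zero for identical windows and at the shift for delayed copies", {
  set.seed(5)
  x <- cumsum(rnorm(90))                  # 3 s at 30 Hz
  r <- lagged_crosscorr(mk_win(x), mk_win(x))
  expect_equal(r$max_correlation, 1, tolerance = 1e-12)
  expect_equal(r$lag_at_max_s, 0)
  # b = a delayed by 0.3 s (9 samples)
  y <- c(rep(x[1], 9), x[1:(90 - 9)])
  r2 <- lagged_crosscorr(mk_win(x), mk_win(y))
  expect_equal(r2$lag_at_max_s, 0.3, tolerance = 1 / 30 + 1e-9)
  # constant series: undefined, flagged
  r3 <- lagged_crosscorr(mk_win(rep(1, 90)), mk_win(x))
  expect_false(r3$ok)
})

test_that("per-lag correlations equal a brute-force Pearson double loop", {
  set.seed(15)
  for (rep_i in 1:5) {
    a <- mk_win(rnorm(75), rnorm(75))
    b <- mk_win(rnorm(75), rnorm(75))
    got <- lagged_crosscorr(a, b)
    K <- 45
    for (ki in seq_along(got$lags)) {
      k <- round(got$lags[ki] * 30)
      ia <- if (k >= 0) 1:(75 - k) else (1 - k):75
      ib <- ia + k
      pear <- function(x, y) {
        n <- length(x)
        sx <- sum(x); sy <- sum(y)
        num <- sum(x * y) - sx * sy / n
        den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
        num / den
      }
      oracle <- mean(c(pear(a$az[ia], b$az[ib]), pear(a$el[ia], b$el[ib])))
      expect_equal(got$correlations[ki], oracle, tolerance = 1e-12)
    }
  }
})

test_that("cross-correlation is symmetric under swapping the two windows", {
  set.seed(25)
  a <- mk_win(cumsum(rnorm(80)), cumsum(rnorm(80)))
  b <- mk_win(cumsum(rnorm(80)), cumsum(rnorm(80)))
  r_ab <- lagged_crosscorr(a, b)
  r_ba <- lagged_crosscorr(b, a)
  expect_equal(r_ab$correlations, rev(r_ba$correlations), tolerance = 1e-12)
  expect_equal(r_ab$max_correlation, r_ba$max_correlation, tolerance = 1e-12)
  expect_equal(r_ab$lag_at_max_s, r_ba$lag_at_max_s, tolerance = 1e-12)
})

test_that("window pairs follow the schedule with a 5 s null offset and drop masked trials", {
  ts <- seq(0, 50 - 1 / 30, by = 1 / 30)
  mk_series <- function(id) gaze_angle_series(id, ts, cumsum(rnorm(length(ts))),
                                              cumsum(rnorm(length(ts))))
  set.seed(35)
  sched <- trial_schedule(rep(c("left_eye", "mouth"), 5), (0:9) * 5)
  p <- mk_series("p"); e <- mk_series("e")
  pairs <- build_window_pairs(p, e, sched)
  expect_lte(length(pairs), 10)
  # last trial's null window would end at 52 s -> dropped
  expect_false(10 %in% vapply(pairs, `[[`, 0L, "window_id"))
  for (pr in pairs) {
    expect_equal(pr$unsync$b$t[1] - pr$sync$b$t[1], 5)
    expect_equal(pr$sync$a$t[1], sched$start_s[pr$window_id])
  }
  # masking a trial's samples drops its pair
  e2 <- e; e2$valid[ts >= 10 & ts < 12] <- FALSE
  pairs2 <- build_window_pairs(p, e2, sched)
  expect_false(3 %in% vapply(pairs2, `[[`, 0L, "window_id"))
})

test_that("per-participant medians agree with a sort-based oracle", {
  res <- data.frame(window_id = 1:5,
                    synchronized = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    max_correlation = c(0.9, 0.4, 0.6, 0.2, 0.8),
                    lag_at_max_s = c(0, 0.5, 0.2, 1, 0.7))
  su <- summarize_per_participant(res)
  expect_equal(su$median_correlation_sync, sort(c(0.9, 0.4, 0.6))[2])
  expect_equal(su$median_lag_sync, 0.2)
  expect_equal(su$median_correlation_unsync, mean(c(0.2, 0.8)))
  expect_true(su$complete)
  one <- res[1, ]
  su1 <- summarize_per_participant(one)
  expect_equal(su1$median_correlation_sync, 0.9)
  expect_false(su1$complete)
})

test_that("Wilcoxon signed-rank normal approximation reproduces small-sample reference p-values", {
  # n = 8 pairs, W = 1 and W = 0
  x <- 1:8
  y1 <- x + c(-1, rep(1, 7)) * c(0.5, 1:7)   # one negative difference, rank 1
  w1 <- wilcoxon_signed_rank(y1, x)
  expect_equal(w1$W, 1)
  expect_equal(round(w1$p, 3), 0.017)
  w0 <- wilcoxon_signed_rank(rep(1, 8), mode = "normal")
  expect_equal(w0$W, 0)
  expect_equal(round(w0$p, 3), 0.012)
  # W at the null mean n(n+1)/4 = 18 gives z = 0 and p = 1
  d <- c(-1, -2, 3, -4, -5, -6, 7, 8)        # positive ranks {3, 7, 8} sum 18
  wm <- wilcoxon_signed_rank(d)
  expect_equal(wm$W, 18)
  expect_equal(wm$z, 0)
  expect_equal(wm$p, 1)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
})

test_that("normal and exact Wilcoxon p-values agree closely in the decision tail for n = 8", {
  # the uncorrected normal approximation tracks the exact distribution to
  # 0.01 wherever the exact p is below 0.10 (the regime where the test
  # decides anything) and to 0.07 across the whole support of W
  for (W in 0:18) {
    # build differences with the required min rank sum, no ties
    signs <- rep(1, 8)
    remaining <- W
    for (r in 8:1) if (remaining >= r) { signs[r] <- -1; remaining <- remaining - r }
    d <- signs * (1:8)
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$W, W)
    ex <- wilcoxon_signed_rank(d, mode = "exact")
    expect_lt(abs(got$p - ex$p), if (ex$p < 0.10) 0.01 else 0.07)
    expect_equal(ex$p, min(1, 2 * psignrank(W, 8)), tolerance = 1e-12)
  }
})

test_that("coupled dyads show recoverable lag and stronger synchronized correlations", {
  su <- dyad_synchrony_medians(seed = 1234, coupling_lag_s = 0.3)
  expect_true(su$complete)
  expect_equal(su$median_lag_sync, 0.3, tolerance = 1 / 30 + 1e-9)
  expect_gt(su$median_correlation_sync, su$median_correlation_unsync)
  expect_lt(su$median_lag_sync, su$median_lag_unsync)
})

test_that("synchrony report aggregates medians and flags underpowered samples", {
  set.seed(45)
  pp <- data.frame(median_correlation_sync = runif(8, 0.5, 0.9),
                   median_correlation_unsync = runif(8, 0.1, 0.5),
                   median_lag_sync = runif(8, 0.1, 0.4),
                   median_lag_unsync = runif(8, 0.4, 1))
  rep_ <- synchrony_report(pp)
  expect_equal(rep_$n_participants, 8)
  expect_false(rep_$underpowered)
  expect_lt(rep_$test_correlation$p, 0.05)
  expect_equal(rep_$median_correlation_sync,
               median(pp$median_correlation_sync))
  w <- capture_warnings(rep3 <- synchrony_report(pp[1:3, ]))
  expect_match(w, "n < 5", all = TRUE)   # both tests warn at n = 3
  expect_true(rep3$underpowered)
  expect_error(synchrony_report(pp[0, ]), "no participants")
})
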