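test_that("eye centers transform rigidly with head pose", {
  ep <- eye_model_params(eye_center_offsets = list(left = c(-3, 0, 0),
                                                   right = c(3, 0, 0)))
  id <- head_pose(diag(3), c(0, 0, 0))
  expect_equal(eye_center_world(id, ep, "left"), c(-3, 0, 0))
  tr <- head_pose(diag(3), c(1, 2, 3))
  expect_equal(eye_center_world(tr, ep, "right"), c(4, 2, 3))
  set.seed(7)
  for (i in 1:20) {
    hp <- head_pose(random_rotation(), rnorm(3, 0, 20))
    d <- dyadgaze:::vnorm(eye_center_world(hp, ep, "left") -
                            eye_center_world(hp, ep, "right"))
    expect_equal(d, 6, tolerance = 1e-9)     # inter-center distance invariant
  }
})

test_that("pupil at the projected eye center gives a camera-ward gaze, horizontal offsets give horizontal gaze", {
  cam <- identity_camera()
  ep <- eye_model_params()
  ec <- c(0, 0, 60)
  # pupil pixel = projection of the eye center: gaze along center -> camera
  g <- gaze_from_pupil(cam, project(cam, ec), ec, ep)
  expect_equal(g$origin, ec)
  expect_equal(g$direction, c(0, 0, -1), tolerance = 1e-9)
  # horizontal-only pixel offset: zero vertical gaze component
  g2 <- gaze_from_pupil(cam, project(cam, ec) + c(8, 0), ec, ep)
  expect_lt(abs(g2$direction[2]), 1e-6)
  expect_gt(g2$direction[1], 0)
  # ray far off the eyeball signals an invalid sample
  expect_error(gaze_from_pupil(cam, c(5000, 5000), ec, ep),
               class = "dyadgaze_pupil_off_eyeball")
})

test_that("noiseless simulated fixations are recovered within 0.05 degrees", {
  cfg <- scene_config(seed = 2)
  ses <- simulate_calibration_session(cfg, include_iris = FALSE)
  ep <- cfg$eye_params
  idx <- round(seq(1, length(ses$times), length.out = 25))
  for (i in idx) {
    ec <- ses$eye_centers$left[i, ]
    g <- gaze_from_pupil(cfg$camera_p,
                         c(ses$obs$pupil_left_u[i], ses$obs$pupil_left_v[i]),
                         ec, ep)
    truth <- ses$gaze_dirs$left[i, ]
    expect_lt(dyadgaze:::angle_between_deg(g$direction, truth), 0.05)
  }
})

test_that("iris unprojection inverts the forward circle projector", {
  set.seed(13)
  cam <- test_camera(center = c(1, -2, 0), target = c(0, 5, 100))
  n_match <- 0
  for (i in 1:200) {
    circ <- random_facing_circle(cam)
    ell <- project_circle(cam, circ)
    cands <- unproject_iris(cam, ell, circ$radius)
    errs <- vapply(cands, function(cc)
      dyadgaze:::vnorm(cc$center - circ$center) +
        min(dyadgaze:::vnorm(cc$normal - circ$normal),
            dyadgaze:::vnorm(cc$normal + circ$normal)), 0)
    if (min(errs) < 1e-6) n_match <- n_match + 1
    # each candidate re-projects onto the input ellipse
    for (cc in cands) {
      e2 <- project_circle(cam, cc)
      expect_lt(dyadgaze:::vnorm(e2$center - ell$center), 1e-6)
      expect_lt(dyadgaze:::vnorm(e2$semi_axes - ell$semi_axes), 1e-6)
    }
  }
  expect_equal(n_match, 200)
  expect_error(unproject_iris(cam, list(center = c(0, 0), semi_axes = c(1, 0),
                                        angle = 0)))
})

test_that("axis-aligned circles project to centered circles and tilt follows b/a = cos(theta) at depth", {
  cam <- identity_camera()
  circ <- circle_candidate(c(0, 0, 80), c(0, 0, -1), 0.6)
  ell <- project_circle(cam, circ)
  expect_equal(ell$center, c(0, 0), tolerance = 1e-9)
  expect_equal(ell$semi_axes[1], ell$semi_axes[2], tolerance = 1e-9)
  cand <- unproject_iris(cam, ell, 0.6)
  for (cc in cand)
    expect_lt(min(dyadgaze:::vnorm(cc$normal - c(0, 0, -1)),
                  dyadgaze:::vnorm(cc$normal + c(0, 0, -1))), 1e-6)
  # near-orthographic: minor/major axis ratio approaches cos(tilt)
  for (th in c(10, 25, 40) * pi / 180) {
    tilted <- circle_candidate(c(0, 0, 5000),
                               c(sin(th), 0, -cos(th)), 0.6)
    e <- project_circle(cam, tilted)
    expect_equal(e$semi_axes[2] / e$semi_axes[1], cos(th), tolerance = 1e-3)
  }
})

test_that("head-facing disambiguation recovers the true iris normal across rig poses", {
  # rig geometry: the camera views the face from ~30 degrees below the
  # (roughly horizontal) gaze line, so the mirror candidate lands far from
  # the facing direction
  cfg <- scene_config(seed = 17)
  cam <- cfg$camera_p
  base <- cfg$pose_p
  set.seed(17)
  n_ok <- 0; n_tot <- 0
  for (i in 1:100) {
    yaw <- runif(1, -30, 30) * pi / 180
    pose <- head_pose(base$rotation %*% rodrigues(c(0, yaw, 0)),
                      base$translation)
    # gaze toward the partner's face region, within ~8 deg of the facing
    gaze_n <- as.numeric(pose$rotation %*%
                           rodrigues(rnorm(3, 0, 0.08)) %*% c(0, 0, 1))
    ctr <- pose$translation + 1 * gaze_n
    if (sum(gaze_n * (camera_center(cam) - ctr)) < 0) next
    circ <- circle_candidate(ctr, gaze_n, 0.6)
    cands <- unproject_iris(cam, project_circle(cam, circ), 0.6)
    pick <- disambiguate_iris(cands, pose, cam)
    n_tot <- n_tot + 1
    if (min(dyadgaze:::vnorm(pick$normal - gaze_n),
            dyadgaze:::vnorm(pick$normal + gaze_n)) < 1e-4)
      n_ok <- n_ok + 1
  }
  expect_gt(n_tot, 80)
  expect_gte(n_ok / n_tot, 0.99)
  # symmetric ambiguous case: normal perpendicular to facing ties toward
  # the camera-ward candidate
  c1 <- circle_candidate(c(0, 0, 50), c(0, 1, 0), 0.6)
  c2 <- circle_candidate(c(0, 0, 50), c(0, -1, 0), 0.6)
  pose0 <- head_pose(diag(3), c(0, 0, 50))
  cam_above <- test_camera(center = c(0, 5, 0), target = c(0, 0, 50))
  pick <- disambiguate_iris(list(c1, c2), pose0, cam_above)
  expect_equal(pick$normal, c1$normal)   # camera-ward tie-break
})

test_that("eye-center calibration recovers a known offset exactly without noise and is a fixed point at truth", {
  true_off <- list(left = c(-3.1, 0.4, -1.0), right = c(3.1, 0.4, -1.0))
  cfg <- scene_config(seed = 5,
                      eye_params = eye_model_params(
                        eye_center_offsets = true_off))
  ses <- simulate_calibration_session(cfg, include_iris = FALSE)
  frames <- calibration_frames(ses, n = 40)
  seed_params <- eye_model_params(eye_center_offsets = list(
    left = c(-3, 0, 0), right = c(3, 0, 0)))
  est <- estimate_eye_center(frames, cfg$camera_p, seed_params)
  for (eye in c("left", "right")) {
    expect_lt(dyadgaze:::vnorm(est[[eye]]$offset - true_off[[eye]]), 0.05)
    expect_lt(est[[eye]]$residual_deg, 1e-3)
  }
  # initial guess already at truth: residual ~ 0, essentially no movement
  est2 <- estimate_eye_center(frames, cfg$camera_p,
                              eye_model_params(eye_center_offsets = true_off))
  expect_lt(dyadgaze:::vnorm(est2$left$offset - true_off$left), 1e-6)
  expect_lt(est2$left$residual_deg, 1e-6)
  expect_error(estimate_eye_center(frames[1:4], cfg$camera_p, seed_params),
               class = "dyadgaze_insufficient_calibration")
})

test_that("eye-center recovery error grows monotonically with pupil noise", {
  errs <- vapply(c(0, 0.5, 3), function(s) {
    med <- vapply(1:5, function(k) {
      cfg <- scene_config(seed = 100 + k, pupil_noise_px = s)
      ses <- simulate_calibration_session(cfg, include_iris = FALSE)
      est <- estimate_eye_center(calibration_frames(ses, 40), cfg$camera_p,
                                 cfg$eye_params)
      dyadgaze:::vnorm(est$left$offset -
                         cfg$eye_params$eye_center_offsets$left)
    }, 0)
    median(med)
  }, 0)
  expect_true(all(diff(errs) >= -1e-9))
})
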