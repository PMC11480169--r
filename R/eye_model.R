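# Two-sphere eye model: the eyeball is a sphere of radius ~1.2 cm rotating
# about a fixed center in the head; the iris is a circle of radius ~0.6 cm
# whose plane is perpendicular to the optical axis.  Gaze is taken as the
# eyeball-center -> pupil axis (no fovea/kappa correction).

#' Eye model parameters
#'
#' @param eyeball_radius eyeball sphere radius, cm (default 1.2, a standard
#'   adult average).
#' @param iris_radius iris circle radius, cm (default 0.6); must be smaller
#'   than the eyeball radius.
#' @param eye_center_offsets named list with `left` and `right` length-3
#'   eye-rotation-center offsets in the face-local frame, cm.
#' @return object of class `eye_model_params`.
#' @export
eye_model_params <- function(eyeball_radius = 1.2, iris_radius = 0.6,
                             eye_center_offsets = list(
                               left  = c(-3.1, 0, -1.0),
                               right = c( 3.1, 0, -1.0))) {
  stopifnot(iris_radius > 0, iris_radius < eyeball_radius,
            all(c("left", "right") %in% names(eye_center_offsets)))
  structure(list(eyeball_radius = eyeball_radius, iris_radius = iris_radius,
                 eye_center_offsets = lapply(eye_center_offsets, as.numeric)),
            class = "eye_model_params")
}

#' Eye rotation center in world coordinates
#'
#' Rigidly transforms the face-local eye-center offset by the head pose.
#'
#' @param head_pose a [head_pose()] (face-to-world rotation + translation).
#' @param params an [eye_model_params()].
#' @param eye `"left"` or `"right"`.
#' @return length-3 world point, cm.
#' @export
eye_center_world <- function(head_pose, params, eye = c("left", "right")) {
  eye <- match.arg(eye)
  as.numeric(head_pose$rotation %*% params$eye_center_offsets[[eye]] +
               head_pose$translation)
}

#' Gaze ray from the imaged pupil center
#'
#' Back-projects the pupil pixel, intersects the viewing ray with the
#' eyeball sphere about the (calibrated) eye rotation center, and takes the
#' near (camera-side) intersection as the 3D pupil.  The gaze ray runs from
#' the rotation center through the pupil.
#'
#' @param camera a [camera_model()].
#' @param pupil_px length-2 pixel coordinates of the pupil center.
#' @param eye_center length-3 world position of the eye rotation center, cm.
#' @param params an [eye_model_params()].
#' @return a [ray3()] with origin at the eye center.  Signals
#'   `dyadgaze_pupil_off_eyeball` when the pupil ray misses the sphere.
#' @export
gaze_from_pupil <- function(camera, pupil_px, eye_center, params) {
  g <- gaze_dirs_from_pupils(camera, matrix(pupil_px, 1),
                             matrix(eye_center, 1), params$eyeball_radius)
  if (!g$valid[1])
    stop(structure(class = c("dyadgaze_pupil_off_eyeball", "error",
                             "condition"),
                   list(message = "pupil ray misses the eyeball sphere",
                        call = sys.call())))
  ray3(eye_center, g$dirs[1, ])
}

# Vectorized pupil -> gaze directions.  pupil_px, centers: n x 2 / n x 3.
gaze_dirs_from_pupils <- function(camera, pupil_px, centers, radius) {
  o <- camera_center(camera)
  d <- back_project_dirs(camera, pupil_px)
  oc <- matrix(o, nrow(centers), 3, byrow = TRUE) - centers
  b <- rowSums(d * oc)
  disc <- b^2 - (rowSums(oc^2) - radius^2)
  valid <- disc >= 0 & !is.na(disc)
  t <- -b - sqrt(pmax(disc, 0))
  pupil3 <- matrix(o, nrow(centers), 3, byrow = TRUE) + d * t
  dirs <- pupil3 - centers
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs[!valid, ] <- NA_real_
  list(dirs = dirs, valid = valid, pupil3 = pupil3)
}

#' Iris ellipse (image-space)
#'
#' @param center length-2 pixel center (u, v).
#' @param semi_axes length-2 `(a, b)` semi-axes in pixels, `a >= b > 0`.
#' @param angle orientation of the major axis, radians.
#' @return object of class `iris_ellipse`.
#' @export
iris_ellipse <- function(center, semi_axes, angle) {
  if (semi_axes[2] <= 0 || semi_axes[1] < semi_axes[2])
    stop("ellipse requires a >= b > 0")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 angle = as.numeric(angle)),
            class = "iris_ellipse")
}

#' 3D circle candidate from iris unprojection
#' @param center length-3 world point, cm.
#' @param normal unit normal of the circle plane.
#' @param radius circle radius, cm.
#' @return object of class `circle_candidate`.
#' @export
circle_candidate <- function(center, normal, radius) {
  structure(list(center = as.numeric(center),
                 normal = normalize(as.numeric(normal)),
                 radius = radius),
            class = "circle_candidate")
}

.intrinsic_matrix <- function(camera) {
  matrix(c(camera$fx, 0, 0,
           0, camera$fy, 0,
           camera$cx, camera$cy, 1), 3, 3)
}

# Homogeneous conic matrix (pixel coords) of an ellipse: p' Q p = 0.
.ellipse_conic <- function(ellipse) {
  th <- ellipse$angle
  Rt <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  M <- Rt %*% diag(1 / ellipse$semi_axes^2) %*% t(Rt)
  ctr <- ellipse$center
  Q <- matrix(0, 3, 3)
  Q[1:2, 1:2] <- M
  Q[1:2, 3] <- -M %*% ctr
  Q[3, 1:2] <- Q[1:2, 3]
  Q[3, 3] <- sum(ctr * (M %*% ctr)) - 1
  Q
}

# Ellipse parameters from a homogeneous conic matrix (must be an ellipse).
.conic_to_ellipse <- function(Q) {
  Q2 <- Q[1:2, 1:2]
  b <- Q[1:2, 3]
  ctr <- as.numeric(solve(Q2, -b))
  f0 <- Q[3, 3] + sum(b * ctr)
  E <- eigen(Q2 / (-f0), symmetric = TRUE)
  if (any(E$values <= 0)) stop("conic is not an ellipse")
  a <- 1 / sqrt(E$values[2])            # eigenvalues descending
  bm <- 1 / sqrt(E$values[1])
  ax <- E$vectors[, 2]
  iris_ellipse(ctr, c(a, bm), atan2(ax[2], ax[1]))
}

#' Forward-project a 3D circle to its image ellipse
#'
#' Exact pinhole image of a circle: the viewing cone through the circle is
#' intersected with the image plane.  Used by the simulator to synthesize
#' iris ellipses and as the forward model that [unproject_iris()] inverts.
#'
#' @param camera a [camera_model()].
#' @param circle a [circle_candidate()] in world coordinates.
#' @return an [iris_ellipse()].
#' @export
project_circle <- function(camera, circle) {
  cc <- as.numeric(camera$rotation %*% circle$center + camera$translation)
  if (cc[3] <= 0)
    stop(structure(class = c("dyadgaze_behind_camera", "error", "condition"),
                   list(message = "circle behind camera", call = sys.call())))
  nc <- as.numeric(camera$rotation %*% circle$normal)
  d0 <- sum(nc * cc)
  M <- d0 * diag(3) - cc %o% nc
  A <- t(M) %*% M - circle$radius^2 * (nc %o% nc)
  K <- .intrinsic_matrix(camera)
  Kinv <- solve(K)
  Q <- t(Kinv) %*% A %*% Kinv
  .conic_to_ellipse(Q)
}

#' Unproject an iris ellipse to its two 3D circle candidates
#'
#' Inverse rendering of the iris: the ellipse defines a viewing cone through
#' the camera center; the two planes cutting that cone in a circle of the
#' given radius yield two candidates differing by the standard two-fold
#' normal ambiguity.  For noiseless input each candidate re-projects exactly
#' onto the ellipse.
#'
#' @param camera a [camera_model()].
#' @param ellipse an [iris_ellipse()].
#' @param iris_radius circle radius, cm.
#' @return list of two [circle_candidate()]s in world coordinates, normals
#'   oriented toward the camera.
#' @export
unproject_iris <- function(camera, ellipse, iris_radius = 0.6) {
  if (ellipse$semi_axes[2] <= 0) stop("degenerate ellipse")
  K <- .intrinsic_matrix(camera)
  A <- t(K) %*% .ellipse_conic(ellipse) %*% K
  E <- eigen(A, symmetric = TRUE)
  lam <- E$values
  if (sum(lam > 0) == 1) {              # normalize sign: two positive, one negative
    lam <- -lam
    E$values <- lam
  }
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  V <- E$vectors[, ord, drop = FALSE]
  if (!(lam[1] >= lam[2] && lam[2] > 0 && lam[3] < 0))
    stop("degenerate ellipse: cone has no circular section")
  l1 <- lam[1]; l2 <- lam[2]; l3 <- lam[3]
  s <- sqrt((l2 - l3) / (l1 - l3))
  Rw <- t(camera$rotation)
  o <- camera_center(camera)
  out <- vector("list", 2)
  for (i in 1:2) {
    g <- c(1, -1)[i] * sqrt(max(0, (l1 - l2) / (l1 - l3)))
    m <- as.numeric(V %*% c(g, 0, s))
    ctr <- as.numeric(V %*% (iris_radius / sqrt(-l1 * l3) *
                               c(g * l3, 0, s * l1)))
    if (ctr[3] < 0) ctr <- -ctr          # circle must lie in front of camera
    if (sum(m * ctr) > 0) m <- -m        # normal faces the camera
    out[[i]] <- circle_candidate(as.numeric(Rw %*% ctr) + o,
                                 as.numeric(Rw %*% m),
                                 iris_radius)
  }
  out
}

#' Resolve the two-fold iris unprojection ambiguity
#'
#' Picks the candidate whose normal agrees best with the head-facing
#' direction; an (exactly) ambiguous case is broken toward the camera.
#'
#' @param candidates list of two [circle_candidate()]s (world frame,
#'   normals camera-ward as returned by [unproject_iris()]).
#' @param head_pose a [head_pose()]; its face +z axis is the facing
#'   direction.
#' @param camera the observing [camera_model()] (tie-break only).
#' @return the selected [circle_candidate()].
#' @export
disambiguate_iris <- function(candidates, head_pose, camera = NULL) {
  facing <- as.numeric(head_pose$rotation[, 3])
  sc <- vapply(candidates, function(cc) sum(cc$normal * facing), 0)
  if (abs(sc[1] - sc[2]) > 1e-12) return(candidates[[which.max(sc)]])
  if (is.null(camera)) return(candidates[[1]])
  o <- camera_center(camera)
  tc <- vapply(candidates,
               function(cc) sum(cc$normal * normalize(o - cc$center)), 0)
  candidates[[which.max(tc)]]
}

#' Estimate per-eye rotation-center offsets from calibration fixations
#'
#' Least-squares fit of the face-local eye-center offset minimizing the
#' angular mismatch between pupil-derived gaze directions and the directions
#' from the candidate eye center to known calibration targets, across frames
#' with known head pose.
#'
#' @param calib_frames list of frames, each a list with elements
#'   `pupil_px` (named list `left`/`right` of length-2 pixel coords),
#'   `pose` (a [head_pose()]) and `target` (length-3 world point the person
#'   was fixating).
#' @param camera the observing [camera_model()].
#' @param params an [eye_model_params()]; its offsets seed the optimizer.
#' @param eyes which eyes to fit.
#' @return named list per eye with `offset` (length-3, cm) and
#'   `residual_deg` (RMS angular residual).  Signals
#'   `dyadgaze_insufficient_calibration` for fewer than 6 usable frames.
#' @export
estimate_eye_center <- function(calib_frames, camera, params,
                                eyes = c("left", "right")) {
  if (length(calib_frames) < 6)
    stop(structure(class = c("dyadgaze_insufficient_calibration", "error",
                             "condition"),
                   list(message = "insufficient calibration data (< 6 frames)",
                        call = sys.call())))
  res <- list()
  for (eye in eyes) {
    px <- t(vapply(calib_frames, function(f) f$pupil_px[[eye]], numeric(2)))
    Rs <- lapply(calib_frames, function(f) f$pose$rotation)
    ts <- t(vapply(calib_frames, function(f) f$pose$translation, numeric(3)))
    tg <- t(vapply(calib_frames, function(f) as.numeric(f$target), numeric(3)))
    resid_fn <- function(theta) {
      ctr <- t(vapply(seq_along(Rs),
                      function(i) as.numeric(Rs[[i]] %*% theta) + ts[i, ],
                      numeric(3)))
      g <- gaze_dirs_from_pupils(camera, px, ctr, params$eyeball_radius)
      u <- tg - ctr
      u <- u / sqrt(rowSums(u^2))
      r <- as.numeric(t(g$dirs - u))
      r[!is.finite(r)] <- 1              # penalize off-eyeball solutions
      r
    }
    fit <- minpack.lm::nls.lm(par = params$eye_center_offsets[[eye]],
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-12, ptol = 1e-12, maxiter = 200))
    theta <- as.numeric(fit$par)
    ctr <- t(vapply(seq_along(Rs),
                    function(i) as.numeric(Rs[[i]] %*% theta) + ts[i, ],
                    numeric(3)))
    g <- gaze_dirs_from_pupils(camera, px, ctr, params$eyeball_radius)
    u <- tg - ctr
    u <- u / sqrt(rowSums(u^2))
    ang <- angle_between_deg(g$dirs, u)
    res[[eye]] <- list(offset = theta,
                       residual_deg = sqrt(mean(ang[is.finite(ang)]^2)))
  }
  res
}
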