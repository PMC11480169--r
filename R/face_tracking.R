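# Head pose from detected facial landmarks and caliper-measured geometry.
#
# Face-local frame: origin at the midpoint between the eyes, +x toward the
# person's left ear... strictly: +x along the left->right eye axis as listed
# in the metrics, +y up, +z out of the face toward the partner (facing
# direction).  All caliper offsets are expressed in this frame, cm.

#' Caliper-measured facial geometry for one person
#'
#' @param person_id character label.
#' @param head_width head width, cm.
#' @param landmark_offsets named list of face-local 3-vectors (cm) for
#'   `left_eye`, `right_eye`, `mouth`, `nose`.
#' @return object of class `face_metrics`.
#' @export
face_metrics <- function(person_id, head_width, landmark_offsets) {
  need <- c("left_eye", "right_eye", "mouth", "nose")
  stopifnot(all(need %in% names(landmark_offsets)), head_width > 0)
  off <- lapply(landmark_offsets[need], as.numeric)
  if (vnorm(off$right_eye - off$left_eye) <= 0)
    stop("inter-eye distance must be positive")
  if (any(vapply(off, vnorm, 0) > head_width))
    stop("landmark offsets must lie within the head width")
  structure(list(person_id = person_id, head_width = head_width,
                 landmark_offsets = off),
            class = "face_metrics")
}

landmark_matrix <- function(metrics) {
  t(vapply(metrics$landmark_offsets, identity, numeric(3)))
}

#' Head pose (face-to-world rigid transform)
#'
#' @param rotation 3x3 face-to-world rotation.
#' @param translation length-3 world position of the face origin, cm.
#' @param timestamp seconds.
#' @param residual RMS landmark re-projection residual, pixels.
#' @return object of class `head_pose`.
#' @export
head_pose <- function(rotation, translation, timestamp = NA_real_,
                      residual = NA_real_) {
  .check_rotation(rotation)
  structure(list(timestamp = timestamp, rotation = rotation,
                 translation = as.numeric(translation), residual = residual),
            class = "head_pose")
}

# Named 4 x 2 matrix of landmark pixels from a frame-observation row/list.
.obs_landmarks <- function(obs) {
  need <- c("left_eye", "right_eye", "mouth", "nose")
  if (!is.null(obs$landmark_px)) {
    m <- t(vapply(obs$landmark_px[need], as.numeric, numeric(2)))
  } else {
    m <- cbind(vapply(need, function(k) obs[[paste0(k, "_u")]], 0),
               vapply(need, function(k) obs[[paste0(k, "_v")]], 0))
  }
  rownames(m) <- need
  m
}

#' Estimate head pose from one frame's landmarks
#'
#' Iterative re-projection least squares (Levenberg-Marquardt) over the
#' rigid transform, seeded either by a warm-start pose or by a closed-form
#' frontal initialization (depth from the apparent inter-eye distance).
#'
#' @param obs one frame's observation: either a list with `landmark_px`
#'   (named list of length-2 pixel coords) or a row of the frame-series
#'   data frame (columns `left_eye_u`, `left_eye_v`, ...).
#' @param metrics a [face_metrics()].
#' @param camera the observing [camera_model()].
#' @param init optional [head_pose()] warm start (e.g. the previous frame).
#' @return a [head_pose()] with the RMS pixel residual.  Signals
#'   `dyadgaze_pose_unavailable` when fewer than 4 finite landmarks exist.
#' @export
estimate_head_pose <- function(obs, metrics, camera, init = NULL) {
  img <- .obs_landmarks(obs)
  if (any(!is.finite(img)))
    stop(structure(class = c("dyadgaze_pose_unavailable", "error",
                             "condition"),
                   list(message = "pose unavailable: fewer than 4 landmarks",
                        call = sys.call())))
  model <- landmark_matrix(metrics)

  if (is.null(init)) {
    o <- camera_center(camera)
    fwd <- as.numeric(t(camera$rotation)[, 3])   # camera optical axis, world
    R0 <- .facing_rotation(-fwd)
    eye_px <- vnorm(img["right_eye", ] - img["left_eye", ])
    eye_cm <- vnorm(metrics$landmark_offsets$right_eye -
                      metrics$landmark_offsets$left_eye)
    depth <- camera$fx * eye_cm / max(eye_px, 1e-6)
    ctr_dir <- back_project_dirs(camera, matrix(colMeans(img), 1))[1, ]
    t0 <- o + ctr_dir * depth / sum(ctr_dir * fwd)
  } else {
    R0 <- init$rotation
    t0 <- init$translation
  }

  resid_fn <- function(theta) {
    R <- rodrigues(theta[1:3]) %*% R0
    p <- model %*% t(R) + matrix(theta[4:6], 4, 3, byrow = TRUE)
    uv <- tryCatch(project(camera, p), dyadgaze_behind_camera = function(e) NULL)
    if (is.null(uv)) return(rep(1e3, 8))
    as.numeric(uv - img)
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0, t0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-14, ptol = 1e-14, maxiter = 100))
  theta <- as.numeric(fit$par)
  R <- rodrigues(theta[1:3]) %*% R0
  rmse <- sqrt(mean(resid_fn(theta)^2))
  ts <- if (!is.null(obs$timestamp)) as.numeric(obs$timestamp)[1] else NA_real_
  head_pose(R, theta[4:6], timestamp = ts, residual = rmse)
}

# Face-to-world rotation whose +z is `facing` and +y as close to world up.
.facing_rotation <- function(facing, up = c(0, 1, 0)) {
  z <- normalize(facing)
  x <- normalize(cross3(up, z))
  y <- cross3(z, x)
  cbind(x, y, z, deparse.level = 0)
}

#' Person's face plane with in-plane landmark coordinates
#'
#' The plane passes through the posed 3D positions of the two eyes and the
#' mouth (three points define it exactly); its origin is their centroid,
#' `basis_u` runs along the left-to-right eye direction, and the normal is
#' oriented along the facing direction (toward the partner/opposing camera).
#' The nose is used for pose estimation but not for the plane.
#'
#' @param pose a [head_pose()].
#' @param metrics a [face_metrics()].
#' @return object of class `face_plane`: fields `owner`, `plane`
#'   ([plane3()]) and `landmarks_2d` (4 x 2 matrix of in-plane cm
#'   coordinates for left_eye, right_eye, mouth, nose).
#' @export
build_face_plane <- function(pose, metrics) {
  pts <- landmark_matrix(metrics) %*% t(pose$rotation) +
    matrix(pose$translation, 4, 3, byrow = TRUE)
  rownames(pts) <- names(metrics$landmark_offsets)
  face_plane_from_points(pts, facing = as.numeric(pose$rotation[, 3]),
                         owner = metrics$person_id)
}

#' Face plane from posed 3D landmark positions
#'
#' Variant of [build_face_plane()] taking world-space landmark points
#' directly (e.g. after cross-camera interpolation of a partner's landmark
#' series).
#'
#' @param points 4 x 3 matrix with rows `left_eye`, `right_eye`, `mouth`,
#'   `nose` (nose optional, used only for its in-plane coordinate).
#' @param facing world direction the face points toward; orients the normal.
#' @param owner person label.
#' @return a `face_plane`.
#' @export
face_plane_from_points <- function(points, facing, owner = NA_character_) {
  le <- points["left_eye", ]; re <- points["right_eye", ]
  mo <- points["mouth", ]
  n <- cross3(re - le, mo - le)
  if (vnorm(n) < 1e-9)
    stop(structure(class = c("dyadgaze_degenerate_plane", "error",
                             "condition"),
                   list(message = "collinear landmarks: degenerate face plane",
                        call = sys.call())))
  n <- normalize(n)
  if (sum(n * facing) < 0) n <- -n
  pl <- plane3(point = (le + re + mo) / 3, normal = n, basis_u = re - le)
  lm2 <- to_plane_coords(pl, points)
  rownames(lm2) <- rownames(points)
  structure(list(owner = owner, plane = pl, landmarks_2d = lm2),
            class = "face_plane")
}
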