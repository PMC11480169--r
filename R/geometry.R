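# Shared 3D world frame, pinhole cameras, planes, rays, visual angles.
#
# World frame convention: origin at the midpoint between the two camera
# centers, right-handed, +y up, +z toward the participant-side camera's
# viewing direction projected on the horizontal plane, units cm.
# Image convention: origin top-left, u right, v down (camera frame is the
# usual computer-vision frame: +x right, +y down, +z forward).

vnorm <- function(x) sqrt(sum(x * x))

normalize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from an axis-angle (Rodrigues) vector
#'
#' @param w numeric length-3 rotation vector; its norm is the rotation angle
#'   in radians, its direction the rotation axis.
#' @return 3x3 rotation matrix.
#' @export
rodrigues <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) {
    K <- skew3(w)
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

.check_rotation <- function(R, tol = 1e-6) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (max(abs(t(R) %*% R - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation must be orthonormal with determinant +1")
  invisible(R)
}

#' Pinhole camera model
#'
#' Extrinsics map world to camera coordinates: `x_cam = R x_world + t`.
#' No lens distortion is modeled; intrinsics are assumed pre-rectified.
#'
#' @param camera_id character label.
#' @param fx,fy focal lengths in pixels (positive).
#' @param cx,cy principal point in pixels (image origin top-left).
#' @param rotation 3x3 world-to-camera rotation.
#' @param translation length-3 world-to-camera translation, cm.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(camera_id, fx, fy, cx, cy, rotation, translation) {
  stopifnot(fx > 0, fy > 0, length(translation) == 3)
  .check_rotation(rotation)
  structure(list(camera_id = camera_id, fx = fx, fy = fy, cx = cx, cy = cy,
                 rotation = rotation, translation = as.numeric(translation)),
            class = "camera_model")
}

#' Construct a camera looking at a target point
#'
#' Builds extrinsics for a camera at `center` whose optical axis passes
#' through `target`, with the image "up" as close to world `up` as possible.
#'
#' @param camera_id label.
#' @param center,target world points, cm.
#' @param fx,fy,cx,cy intrinsics in pixels.
#' @param up world up direction (default +y).
#' @return a [camera_model()].
#' @export
camera_look_at <- function(camera_id, center, target, fx, fy, cx, cy,
                           up = c(0, 1, 0)) {
  z_c <- normalize(target - center)
  x_c <- normalize(cross3(-up, z_c))     # camera +y is down
  y_c <- cross3(z_c, x_c)
  R <- rbind(x_c, y_c, z_c)
  dimnames(R) <- NULL
  camera_model(camera_id, fx, fy, cx, cy, R, -R %*% center)
}

#' Camera center in world coordinates
#' @param camera a [camera_model()].
#' @return length-3 world point, cm.
#' @export
camera_center <- function(camera) {
  as.numeric(-t(camera$rotation) %*% camera$translation)
}

#' Project world points through a pinhole camera
#'
#' @param camera a [camera_model()].
#' @param point_world length-3 vector or n x 3 matrix of world points, cm.
#' @return length-2 vector or n x 2 matrix of pixel coordinates (u, v).
#'   Signals a condition of class `dyadgaze_behind_camera` if any point has
#'   nonpositive depth in the camera frame.
#' @export
project <- function(camera, point_world) {
  p <- if (is.matrix(point_world)) point_world else matrix(point_world, 1)
  pc <- p %*% t(camera$rotation) +
    matrix(camera$translation, nrow(p), 3, byrow = TRUE)
  if (any(pc[, 3] <= 1e-9))
    stop(structure(class = c("dyadgaze_behind_camera", "error", "condition"),
                   list(message = "point behind camera", call = sys.call())))
  uv <- cbind(camera$cx + camera$fx * pc[, 1] / pc[, 3],
              camera$cy + camera$fy * pc[, 2] / pc[, 3])
  if (is.matrix(point_world)) uv else as.numeric(uv)
}

# Vectorized world-frame ray directions for an n x 2 pixel matrix.
back_project_dirs <- function(camera, px) {
  d <- cbind((px[, 1] - camera$cx) / camera$fx,
             (px[, 2] - camera$cy) / camera$fy,
             1)
  dw <- d %*% camera$rotation           # = t(R) applied to rows
  dw / sqrt(rowSums(dw^2))
}

#' Back-project a pixel to a world-frame viewing ray
#'
#' @param camera a [camera_model()].
#' @param pixel length-2 (u, v) pixel coordinates.
#' @return a [ray3()] from the camera center through the pixel.
#' @export
back_project <- function(camera, pixel) {
  dw <- back_project_dirs(camera, matrix(pixel, 1))
  ray3(camera_center(camera), as.numeric(dw))
}

#' 3D ray
#' @param origin length-3 world point, cm.
#' @param direction length-3 direction; normalized on construction.
#' @return object of class `ray3`.
#' @export
ray3 <- function(origin, direction) {
  structure(list(origin = as.numeric(origin),
                 direction = normalize(as.numeric(direction))),
            class = "ray3")
}

#' 3D plane with an in-plane orthonormal basis
#'
#' `basis_u`, `basis_v`, `normal` form a right-handed orthonormal triad
#' (`basis_u x basis_v = normal`).  If the basis is omitted an arbitrary one
#' is constructed.
#'
#' @param point a point on the plane, cm.
#' @param normal plane normal; normalized on construction.
#' @param basis_u optional in-plane direction (orthogonalized and
#'   normalized against the normal).
#' @return object of class `plane3`.
#' @export
plane3 <- function(point, normal, basis_u = NULL) {
  n <- normalize(as.numeric(normal))
  if (is.null(basis_u)) {
    seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- normalize(seed - sum(seed * n) * n)
  } else {
    u <- as.numeric(basis_u)
    u <- normalize(u - sum(u * n) * n)
  }
  v <- cross3(n, u)
  structure(list(point = as.numeric(point), normal = n,
                 basis_u = u, basis_v = v),
            class = "plane3")
}

#' Intersect a forward ray with a plane
#'
#' @param ray a [ray3()].
#' @param plane a [plane3()].
#' @param eps parallelism tolerance on |direction . normal| (default 1e-8).
#' @return length-3 world intersection point, cm.  Signals
#'   `dyadgaze_parallel_ray` when the ray is (near) parallel to the plane and
#'   `dyadgaze_behind_origin` when the intersection has t < 0.
#' @export
line_plane_intersection <- function(ray, plane, eps = 1e-8) {
  den <- sum(ray$direction * plane$normal)
  if (abs(den) <= eps)
    stop(structure(class = c("dyadgaze_parallel_ray", "error", "condition"),
                   list(message = "ray parallel to plane: no intersection",
                        call = sys.call())))
  t <- sum((plane$point - ray$origin) * plane$normal) / den
  if (t < 0)
    stop(structure(class = c("dyadgaze_behind_origin", "error", "condition"),
                   list(message = "intersection behind ray origin",
                        call = sys.call())))
  ray$origin + t * ray$direction
}

# Vectorized ray-plane intersection: origins, dirs are n x 3; returns list
# with n x 3 points and a validity flag (FALSE: parallel or behind origin).
intersect_rays_plane <- function(origins, dirs, plane, eps = 1e-8) {
  den <- dirs %*% plane$normal
  num <- (matrix(plane$point, nrow(origins), 3, byrow = TRUE) - origins) %*%
    plane$normal
  t <- as.numeric(num) / as.numeric(den)
  ok <- abs(as.numeric(den)) > eps & t >= 0 & is.finite(t)
  pts <- origins + dirs * t
  pts[!ok, ] <- NA_real_
  list(points = pts, valid = ok)
}

#' In-plane 2D coordinates of world points
#'
#' Points are first orthogonally projected onto the plane.
#'
#' @param plane a [plane3()].
#' @param point_world length-3 vector or n x 3 matrix.
#' @return length-2 vector or n x 2 matrix of (x, y) cm in the plane basis.
#' @export
to_plane_coords <- function(plane, point_world) {
  p <- if (is.matrix(point_world)) point_world else matrix(point_world, 1)
  d <- p - matrix(plane$point, nrow(p), 3, byrow = TRUE)
  xy <- cbind(d %*% plane$basis_u, d %*% plane$basis_v)
  if (is.matrix(point_world)) xy else as.numeric(xy)
}

#' World point from in-plane coordinates
#' @param plane a [plane3()].
#' @param xy length-2 vector or n x 2 matrix of in-plane coordinates, cm.
#' @return length-3 vector or n x 3 matrix of world points.
#' @export
from_plane_coords <- function(plane, xy) {
  m <- if (is.matrix(xy)) xy else matrix(xy, 1)
  p <- matrix(plane$point, nrow(m), 3, byrow = TRUE) +
    m[, 1] %o% plane$basis_u + m[, 2] %o% plane$basis_v
  if (is.matrix(xy)) p else as.numeric(p)
}

#' Visual angle subtended by a linear offset
#'
#' `atan(offset / distance)` in degrees: the standard unit of eye-tracking
#' accuracy.
#'
#' @param offset_cm linear offset(s) on the target surface, cm (>= 0).
#' @param distance_cm viewing distance(s), cm (> 0).
#' @return angle(s) in degrees.
#' @export
visual_angle <- function(offset_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("distance_cm must be positive")
  if (any(offset_cm < 0)) stop("offset_cm must be nonnegative")
  atan(offset_cm / distance_cm) * 180 / pi
}

#' Linear offset subtending a given visual angle
#' @param angle_deg angle(s) in degrees.
#' @param distance_cm viewing distance(s), cm (> 0).
#' @return offset(s) in cm; inverse of [visual_angle()].
#' @export
offset_from_angle <- function(angle_deg, distance_cm) {
  if (any(distance_cm <= 0)) stop("distance_cm must be positive")
  tan(angle_deg * pi / 180) * distance_cm
}

# Angle in degrees between two sets of direction vectors (rows).
angle_between_deg <- function(a, b) {
  a <- if (is.matrix(a)) a else matrix(a, 1)
  b <- if (is.matrix(b)) b else matrix(b, 1)
  ca <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}
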