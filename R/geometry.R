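# Coordinate conventions
# ----------------------
# Right-handed world frame: +x to the observer's right, +y up, +z the
# forward gaze direction at zero azimuth/elevation.  Azimuth is positive to
# the right and wraps on the half-open interval (-180, 180]; elevation is
# positive up in [-90, 90].  All angles are degrees, all lengths metres
# unless a function says otherwise.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Unit view direction from spherical visual-field coordinates
#'
#' Converts azimuth/elevation (degrees of visual field, the retinocentric
#' chart with elevation as latitude and azimuth as longitude) to unit
#' direction vectors in the observer's frame:
#' `x = cos(el) sin(az)`, `y = sin(el)`, `z = cos(el) cos(az)`.
#'
#' @param azimuth_deg Numeric vector, degrees in (-180, 180].
#' @param elevation_deg Numeric vector, degrees in [-90, 90]. Recycled
#'   against `azimuth_deg`.
#' @return An `n x 3` numeric matrix of unit vectors with columns
#'   `x`, `y`, `z`.
#' @seealso [spherical_from_direction()] for the inverse.
#' @export
#' @examples
#' direction_from_spherical(60, 30)
direction_from_spherical <- function(azimuth_deg, elevation_deg) {
  n <- max(length(azimuth_deg), length(elevation_deg))
  az <- rep_len(as.numeric(azimuth_deg), n)
  el <- rep_len(as.numeric(elevation_deg), n)
  if (anyNA(az) || anyNA(el)) {
    stop("azimuth/elevation must be finite", call. = FALSE)
  }
  if (any(az <= -180 - 1e-12) || any(az > 180 + 1e-12)) {
    stop("azimuth out of range (-180, 180]", call. = FALSE)
  }
  if (any(el < -90 - 1e-12) || any(el > 90 + 1e-12)) {
    stop("elevation out of range [-90, 90]", call. = FALSE)
  }
  a <- az * DEG2RAD
  e <- el * DEG2RAD
  cbind(x = cos(e) * sin(a), y = sin(e), z = cos(e) * cos(a))
}

#' Spherical visual-field coordinates of direction vectors
#'
#' Inverse of [direction_from_spherical()]; scale-invariant, so any
#' non-zero vector may be passed.
#'
#' @param direction Numeric length-3 vector or `n x 3` matrix.
#' @return A tibble with columns `azimuth` and `elevation` (degrees).
#' @export
spherical_from_direction <- function(direction) {
  d <- as_direction_matrix(direction)
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-300)) stop("zero direction vector", call. = FALSE)
  d <- d / nrm
  el <- asin(pmin(1, pmax(-1, d[, 2]))) * RAD2DEG
  az <- atan2(d[, 1], d[, 3]) * RAD2DEG
  # atan2 returns [-180, 180]; fold -180 onto +180 for the half-open range
  az[az <= -180] <- 180
  tibble::tibble(azimuth = az, elevation = el)
}

as_direction_matrix <- function(v) {
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 3)
    v
  } else {
    stopifnot(length(v) == 3)
    matrix(as.numeric(v), ncol = 3)
  }
}

normalize_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

# --- Poses -----------------------------------------------------------------

#' Rigid pose (position + rotation)
#'
#' A pose maps local coordinates into the parent frame:
#' `p_parent = position + rotation %*% p_local`.  The rotation must be a
#' proper orthonormal 3x3 matrix (checked to 1e-9).
#'
#' @param position Numeric length-3, metres.
#' @param rotation 3x3 rotation matrix; defaults to identity.
#' @return An object of class `pose`.
#' @export
pose <- function(position = c(0, 0, 0), rotation = diag(3)) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3)
  rotation <- as.matrix(rotation)
  check_rotation(rotation)
  structure(list(position = position, rotation = rotation), class = "pose")
}

check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || anyNA(R)) {
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(R) - diag(3))) > tol * 1e3 || abs(det(R) - 1) > tol * 1e3) {
    stop("rotation must be orthonormal with det +1", call. = FALSE)
  }
  invisible(R)
}

#' @export
print.pose <- function(x, ...) {
  cat("<pose> position (m):", format(x$position, digits = 6), "\n")
  ypr <- euler_from_rotation(x$rotation)
  cat("       rotation (deg, x-y-z):", format(ypr, digits = 6), "\n")
  invisible(x)
}

#' Identity pose
#' @return A `pose` at the origin with identity orientation.
#' @export
pose_identity <- function() pose()

#' Compose two poses
#'
#' `transform_pose(a, b)` is the pose of `b` expressed through `a`:
#' applying the result equals applying `a` after `b`
#' (`R = Ra Rb`, `t = ta + Ra tb`).  Identity is neutral and
#' `transform_pose(p, pose_inverse(p))` is the identity.
#'
#' @param a,b Poses.
#' @return A `pose`.
#' @export
transform_pose <- function(a, b) {
  stopifnot(inherits(a, "pose"), inherits(b, "pose"))
  pose(
    position = a$position + as.numeric(a$rotation %*% b$position),
    rotation = a$rotation %*% b$rotation
  )
}

#' Invert a pose
#' @param p A `pose`.
#' @return The inverse `pose`.
#' @export
pose_inverse <- function(p) {
  stopifnot(inherits(p, "pose"))
  Rt <- t(p$rotation)
  pose(position = -as.numeric(Rt %*% p$position), rotation = Rt)
}

#' Apply a pose to points
#' @param p A `pose`.
#' @param pts Length-3 vector or `n x 3` matrix of local points.
#' @return Transformed points, same shape convention (`n x 3` matrix).
#' @export
pose_apply <- function(p, pts) {
  m <- as_direction_matrix(pts)
  sweep(m %*% t(p$rotation), 2, p$position, `+`)
}

# Elementary rotations (degrees)
rot_x <- function(a) {
  a <- a * DEG2RAD
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- a * DEG2RAD
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  a <- a * DEG2RAD
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from Euler angles
#'
#' Rig configuration files give orientations as three angles in degrees,
#' `rotation_deg = c(rx, ry, rz)`, composed as `R = Rz(rz) Ry(ry) Rx(rx)`
#' (extrinsic x-y-z, equivalently intrinsic z-y-x yaw-pitch-roll).
#'
#' @param rx,ry,rz Angles in degrees about the x, y and z axes.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_euler <- function(rx = 0, ry = 0, rz = 0) {
  rot_z(rz) %*% rot_y(ry) %*% rot_x(rx)
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [rotation_from_euler()] (degenerate at `ry = +/-90`, where
#' `rx` is set to 0).
#' @param R 3x3 rotation matrix.
#' @return Numeric `c(rx, ry, rz)` in degrees.
#' @export
euler_from_rotation <- function(R) {
  check_rotation(R)
  sy <- -R[3, 1]
  if (abs(sy) > 1 - 1e-12) {
    ry <- asin(pmin(1, pmax(-1, sy)))
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  } else {
    ry <- asin(sy)
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  }
  c(rx = rx, ry = ry, rz = rz) * RAD2DEG
}

# --- Quaternions (internal; pose averaging and slerp) ----------------------

quat_from_rotation <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q / sqrt(sum(q^2))
}

rotation_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Chordal L2 mean of unit quaternions: principal eigenvector of sum(q q^T),
# sign-aligned to the first quaternion.
quat_mean <- function(qs) {
  qs <- lapply(qs, function(q) if (sum(q * qs[[1]]) < 0) -q else q)
  M <- Reduce(`+`, lapply(qs, function(q) tcrossprod(q)))
  eigen(M, symmetric = TRUE)$vectors[, 1]
}

quat_slerp <- function(q0, q1, s) {
  if (sum(q0 * q1) < 0) q1 <- -q1
  d <- pmin(1, pmax(-1, sum(q0 * q1)))
  th <- acos(d)
  if (th < 1e-12) return(q0)
  q <- (sin((1 - s) * th) * q0 + sin(s * th) * q1) / sin(th)
  q / sqrt(sum(q^2))
}

# --- Display and observer specifications -----------------------------------

#' Physical display specification
#'
#' A flat panel described by the pose of its centre (local `+x` right,
#' `+y` up, `+z` the normal toward the viewable side), its physical width
#' and height in metres and its pixel resolution.  Pixels need not be
#' square; no aspect consistency between physical size and resolution is
#' enforced.
#'
#' @param name Display name (used in rig files and error messages).
#' @param pose A [pose()] of the panel centre in the world frame.
#' @param width,height Physical size, metres, > 0.
#' @param resolution_x,resolution_y Pixel counts, > 0.
#' @return An object of class `display_spec`.
#' @export
display_spec <- function(name, pose, width, height, resolution_x, resolution_y) {
  stopifnot(inherits(pose, "pose"))
  if (!is.character(name) || length(name) != 1) stop("name must be a string")
  if (width <= 0 || height <= 0) stop("display size must be positive")
  if (resolution_x < 1 || resolution_y < 1) stop("resolution must be positive")
  structure(
    list(
      name = name, pose = pose,
      width = as.numeric(width), height = as.numeric(height),
      resolution_x = as.integer(resolution_x),
      resolution_y = as.integer(resolution_y)
    ),
    class = "display_spec"
  )
}

#' @export
print.display_spec <- function(x, ...) {
  cat(sprintf(
    "<display_spec> '%s' %.3f x %.3f m, %d x %d px\n",
    x$name, x$width, x$height, x$resolution_x, x$resolution_y
  ))
  print(x$pose)
  invisible(x)
}

#' Observer specification
#'
#' @param pose A [pose()]: position of the cyclopean eye and orientation of
#'   the head frame in the world.
#' @param interpupillary_distance Metres, >= 0; used only by the stereo path.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(pose = pose_identity(), interpupillary_distance = 0) {
  stopifnot(inherits(pose, "pose"))
  if (interpupillary_distance < 0) stop("interpupillary distance must be >= 0")
  structure(
    list(pose = pose, interpupillary_distance = as.numeric(interpupillary_distance)),
    class = "observer_spec"
  )
}

#' Ray direction from the observer through display pixels
#'
#' Treats the display as a window: texture coordinates `(u, v)` in
#' `[0, 1]^2` (u rightward, v downward in the image convention, pixel
#' `(i, j)` at `u = (i + 1/2)/res_x`, `v = (j + 1/2)/res_y`) locate the
#' physical point `q = centre + R ((u - 1/2) w, (1/2 - v) h, 0)` on the
#' panel, and the returned unit vector is `(q - observer) / |q - observer|`.
#'
#' @param display A [display_spec()].
#' @param observer An [observer_spec()] (or a [pose()], taken as its pose).
#' @param u,v Numeric vectors in `[0, 1]` (recycled to a common length).
#' @return `n x 3` matrix of unit direction vectors in the world frame.
#' @export
pixel_to_direction <- function(display, observer, u, v) {
  stopifnot(inherits(display, "display_spec"))
  obs_pos <- observer_position(observer)
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  local <- cbind((u - 0.5) * display$width, (0.5 - v) * display$height, 0)
  q <- pose_apply(display$pose, local)
  d <- sweep(q, 2, obs_pos, `-`)
  dist <- sqrt(rowSums(d^2))
  if (any(dist < 1e-12)) {
    stop("observer coincides with a display point", call. = FALSE)
  }
  d / dist
}

observer_position <- function(observer) {
  if (inherits(observer, "observer_spec")) observer$pose$position
  else if (inherits(observer, "pose")) observer$position
  else stop("observer must be an observer_spec or pose")
}

#' Texture coordinates of every pixel of a display
#'
#' @param display A [display_spec()].
#' @return A list with vectors `u`, `v` (length `res_x * res_y`, column-major
#'   over rows of the image: row index fastest) and the image dimensions.
#' @keywords internal
display_pixel_grid <- function(display) {
  nx <- display$resolution_x
  ny <- display$resolution_y
  # image matrix is ny rows x nx cols; fill column-major (row fastest)
  j <- rep(seq_len(ny) - 1L, times = nx)
  i <- rep(seq_len(nx) - 1L, each = ny)
  list(u = (i + 0.5) / nx, v = (j + 0.5) / ny, ny = ny, nx = nx)
}
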