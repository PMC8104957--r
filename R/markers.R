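# Square fiducial markers: a 4x4-bit payload inside a one-cell black
# border (6x6 cells over the marker side), surrounded by a one-cell white
# quiet zone.  The dictionary is generated deterministically in code --
# candidate 16-bit patterns are scanned in numeric order and kept when all
# four rotations are mutually distinct (so orientation is decodable) and
# every rotation is at Hamming distance >= 4 from every rotation of every
# previously accepted pattern -- so synthetic tests are fully
# self-contained.
#
# Frames and image conventions used throughout calibration:
#   camera: +x right, +y up, +z forward (optical axis);
#   continuous image coordinates (u, v) in pixels, origin at the top-left
#   corner, u rightward, v DOWNWARD; projection u = cx + fx X/Z,
#   v = cy - fy Y/Z;
#   marker local frame: +x right and +y up as seen on the printed face,
#   +z into the face, so an upright frontoparallel marker facing the
#   camera has identity rotation.  Corners are ordered from the pattern's
#   top-left, clockwise as seen in the image.

MARKER_DICT_SIZE <- 32L

rotate_bits <- function(m) t(m[nrow(m):1, , drop = FALSE])

marker_dictionary <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    accepted <- list()
    rots_of <- function(m) {
      r1 <- rotate_bits(m); r2 <- rotate_bits(r1); r3 <- rotate_bits(r2)
      list(m, r1, r2, r3)
    }
    pool <- matrix(integer(0), nrow = 16)   # columns: rotations of accepted
    id <- 0L
    while (length(accepted) < MARKER_DICT_SIZE && id < 65536L) {
      m <- matrix(as.integer(intToBits(id)[1:16]), 4, 4)
      rs <- rots_of(m)
      vecs <- vapply(rs, as.vector, integer(16))
      ok <- TRUE
      # rotations of the pattern must be mutually distant (orientation
      # decodable) and distant from every rotation already in the pool
      for (a in 1:3) for (b in (a + 1):4) {
        if (sum(vecs[, a] != vecs[, b]) < 4L) ok <- FALSE
      }
      if (ok && ncol(pool)) {
        for (r in 1:4) {
          if (min(colSums(pool != vecs[, r])) < 4L) { ok <- FALSE; break }
        }
      }
      if (ok) {
        accepted[[length(accepted) + 1L]] <- m
        pool <- cbind(pool, vecs)
      }
      id <- id + 1L
    }
    cache <<- accepted
    cache
  }
})

#' Payload bit pattern of a dictionary marker
#'
#' @param id Marker id, 0-based, below the dictionary size (32).
#' @return 4x4 integer matrix of bits (1 = white cell); row 1 is the top
#'   of the upright pattern.
#' @export
marker_pattern <- function(id) {
  dict <- marker_dictionary()
  if (id < 0 || id >= length(dict)) {
    stop("marker id must be in 0..", length(dict) - 1)
  }
  dict[[id + 1L]]
}

# 6x6 cell grid: black border + payload. 0 = black, 1 = white.
marker_cells <- function(id) {
  cells <- matrix(0L, 6, 6)
  cells[2:5, 2:5] <- marker_pattern(id)
  cells
}

#' Pinhole camera intrinsics
#'
#' @param focal_x,focal_y Focal lengths in pixels, > 0.
#' @param cx,cy Principal point, continuous pixel coordinates.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal_x, focal_y = focal_x, cx, cy) {
  if (focal_x <= 0 || focal_y <= 0) stop("focal lengths must be positive")
  structure(list(focal_x = focal_x, focal_y = focal_y, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

# Project camera-frame points (n x 3) to continuous image coordinates.
project_camera <- function(intrinsics, p) {
  p <- as_direction_matrix(p)
  if (any(p[, 3] <= 0)) stop("point behind the camera")
  cbind(u = intrinsics$cx + intrinsics$focal_x * p[, 1] / p[, 3],
        v = intrinsics$cy - intrinsics$focal_y * p[, 2] / p[, 3])
}

# Local coordinates of the four marker corners (pattern top-left first,
# clockwise in the image for a front-facing marker).
marker_corners_local <- function(side) {
  h <- side / 2
  rbind(c(-h, h, 0), c(h, h, 0), c(h, -h, 0), c(-h, -h, 0))
}

#' Project the ground-truth corners of a posed marker
#'
#' @param marker_pose [pose()] of the marker in the camera frame.
#' @param side Marker side (outer black border), metres.
#' @param intrinsics [camera_intrinsics()].
#' @return 4x2 matrix of `(u, v)` image coordinates, pattern top-left
#'   first, clockwise.
#' @export
project_marker_corners <- function(marker_pose, side, intrinsics) {
  project_camera(intrinsics, pose_apply(marker_pose, marker_corners_local(side)))
}

#' Render a synthetic photograph of fiducial markers
#'
#' Raycasts each pixel of a pinhole camera against the marker planes
#' (pattern plus a one-cell white quiet zone) over a uniform background,
#' with supersampling for realistically soft edges.  This is the package's
#' test-fixture generator for the calibration pipeline; it shares no code
#' path with [detect_markers()] beyond the projection conventions.
#'
#' @param markers List of entries `list(id = , side = , pose = <pose in
#'   camera frame>)`.
#' @param intrinsics [camera_intrinsics()].
#' @param width,height Photo size, pixels.
#' @param background Background luminance (default 0.5).
#' @param supersample Sub-rays per pixel edge (default 3).
#' @return An `rw_image` photograph.
#' @export
render_marker_photo <- function(markers, intrinsics, width, height,
                                background = 0.5, supersample = 3) {
  ss <- as.integer(supersample)
  w2 <- width * ss; h2 <- height * ss
  u <- (rep(seq_len(w2), each = h2) - 0.5) / ss
  v <- (rep(seq_len(h2), times = w2) - 0.5) / ss
  d <- cbind((u - intrinsics$cx) / intrinsics$focal_x,
             -(v - intrinsics$cy) / intrinsics$focal_y,
             1)
  best_t <- rep(Inf, nrow(d))
  val <- rep(background, nrow(d))
  for (mk in markers) {
    Rt <- t(mk$pose$rotation)
    o_m <- as.numeric(Rt %*% (-mk$pose$position))
    d_m <- d %*% mk$pose$rotation
    tz <- ifelse(abs(d_m[, 3]) < 1e-15, Inf, -o_m[3] / d_m[, 3])
    X <- o_m[1] + d_m[, 1] * tz
    Y <- o_m[2] + d_m[, 2] * tz
    cell <- mk$side / 6
    half_q <- mk$side / 2 + cell            # include quiet zone
    hit <- is.finite(tz) & tz > RAY_EPS & tz < best_t &
      abs(X) <= half_q & abs(Y) <= half_q
    if (!any(hit)) next
    cells <- marker_cells(mk$id)
    cx <- 1L + pmin(5L, pmax(0L, floor((X[hit] + mk$side / 2) / cell)))
    ry <- 1L + pmin(5L, pmax(0L, floor((mk$side / 2 - Y[hit]) / cell)))
    inside <- abs(X[hit]) <= mk$side / 2 & abs(Y[hit]) <= mk$side / 2
    lum <- rep(1, sum(hit))                 # quiet zone white
    lum[inside] <- cells[cbind(ry[inside], cx[inside])]
    best_t[hit] <- tz[hit]
    val[hit] <- lum
  }
  fine <- matrix(val, nrow = h2, ncol = w2)
  if (ss > 1) {
    idx <- function(k) seq(k, by = ss, length.out = height)
    acc <- matrix(0, height, width)
    for (a in seq_len(ss)) for (b in seq_len(ss)) {
      acc <- acc + fine[seq(a, by = ss, length.out = height),
                        seq(b, by = ss, length.out = width)]
    }
    fine <- acc / (ss * ss)
  }
  rw_image(fine)
}
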