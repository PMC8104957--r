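# Marker detection and display-pose recovery.  A photograph of the rig
# with fiducial markers on the displays (and optionally one on the
# observer) is enough to recover the pose of every display relative to the
# observer, closing the loop photo -> rig config -> rendering.

#' Detect fiducial markers in a photograph
#'
#' Thresholds the image, extracts connected dark components, fits a convex
#' quadrilateral to each candidate, decodes the 4x4 payload against the
#' packaged dictionary (all four rotations), and refines the corners to
#' sub-pixel precision by intersecting least-squares line fits to the
#' border edge crossings.  Uniform images yield an empty result.
#'
#' @param photo An `rw_image` / numeric matrix in `[0, 1]` (colour arrays
#'   are averaged to luminance).
#' @param min_side Minimum apparent marker side in pixels (default 12).
#' @return List of observations `list(marker_id = , corners = <4x2 matrix,
#'   pattern top-left first, clockwise>)`; empty list if none.
#' @export
detect_markers <- function(photo, min_side = 12) {
  if (is.array(photo) && length(dim(photo)) == 3) {
    photo <- apply(photo[, , 1:min(3, dim(photo)[3]), drop = FALSE], c(1, 2), mean)
  }
  m <- unclass(photo)
  if (!is.matrix(m) || !is.numeric(m) || anyNA(m)) {
    stop("photo must be a finite numeric matrix")
  }
  rng <- range(m)
  if (diff(rng) < 0.05) return(list())    # uniform image: no structure
  th <- mean(rng)
  dark <- (m < th) * 1
  labels <- EBImage::bwlabel(dark)
  n_lab <- max(labels)
  if (n_lab == 0) return(list())
  areas <- tabulate(labels[labels > 0], nbins = n_lab)
  out <- list()
  for (lab in which(areas >= min_side^2 * 0.5 & areas <= 0.9 * length(m))) {
    px <- which(labels == lab, arr.ind = TRUE)
    # continuous image coordinates of pixel centres
    pts <- cbind(u = px[, 2] - 0.5, v = px[, 1] - 0.5)
    quad <- fit_quad(pts)
    if (is.null(quad)) next
    obs <- decode_quad(m, th, quad, min_side)
    if (is.null(obs)) next
    obs$corners <- refine_corners(m, th, obs$corners)
    out[[length(out) + 1L]] <- obs
  }
  out
}

# Fit 4 corner points to a convex blob: farthest-point heuristic on the
# convex hull.  Returns a 4x2 matrix in clockwise image order (v down), or
# NULL for degenerate blobs.
fit_quad <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 4) return(NULL)
  ctr <- colMeans(hull)
  d2 <- function(a, b) sum((a - b)^2)
  i1 <- which.max(apply(hull, 1, d2, b = ctr))
  p1 <- hull[i1, ]
  i3 <- which.max(apply(hull, 1, d2, b = p1))
  p3 <- hull[i3, ]
  # signed distance to the diagonal p1-p3
  dvec <- p3 - p1
  nrmv <- c(-dvec[2], dvec[1])
  s <- as.numeric((hull - matrix(p1, nrow(hull), 2, byrow = TRUE)) %*% nrmv)
  if (max(s) <= 0 || min(s) >= 0) return(NULL)
  p2 <- hull[which.max(s), ]
  p4 <- hull[which.min(s), ]
  quad <- rbind(p1, p2, p3, p4)
  # order clockwise in image coordinates (v downward)
  ctr <- colMeans(quad)
  ang <- atan2(quad[, 2] - ctr[2], quad[, 1] - ctr[1])
  quad <- quad[order(ang), , drop = FALSE]
  if (abs(polygon_area(quad)) < 9) return(NULL)
  quad
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# Homography mapping (x, y) plane coordinates to image (u, v) via DLT.
homography_dlt <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (k in seq_len(n)) {
    x <- src[k, 1]; y <- src[k, 2]; u <- dst[k, 1]; v <- dst[k, 2]
    A[2 * k - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * k, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  matrix(h, 3, 3, byrow = TRUE)
}

apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

# Decode the payload of a candidate quad; returns observation with corners
# reordered so the first is the pattern's top-left, or NULL.
decode_quad <- function(m, th, quad, min_side) {
  side_px <- min(sqrt(rowSums((quad - quad[c(2:4, 1), ])^2)))
  if (side_px < min_side) return(NULL)
  # cell-grid coordinates: marker spans [0, 6] x [0, 6]
  H <- homography_dlt(cbind(c(0, 6, 6, 0), c(0, 0, 6, 6)), quad)
  sub <- c(0.3, 0.5, 0.7)
  offs <- expand.grid(dx = sub, dy = sub)
  read_cell <- function(r, c) {
    p <- apply_homography(H, cbind(c - 1 + offs$dx, r - 1 + offs$dy))
    ri <- pmin(nrow(m), pmax(1, round(p[, 2] + 0.5)))
    ci <- pmin(ncol(m), pmax(1, round(p[, 1] + 0.5)))
    mean(m[cbind(ri, ci)] >= th)
  }
  grid <- outer(1:6, 1:6, Vectorize(function(r, c) read_cell(r, c)))
  border <- c(grid[1, ], grid[6, ], grid[2:5, 1], grid[2:5, 6])
  if (mean(border < 0.5) < 0.9) return(NULL)    # border must be black
  bits <- (grid[2:5, 2:5] >= 0.5) * 1L
  dict <- marker_dictionary()
  cand <- bits
  for (rot in 0:3) {
    hit <- which(vapply(dict, function(p) all(p == cand), TRUE))
    if (length(hit) == 1) {
      # corner k of the quad corresponds to pattern corner (k + rot - 1);
      # invert that assignment to list corners pattern-top-left first
      ord <- ((seq_len(4) - 1 + rot) %% 4) + 1
      corners <- quad[match(1:4, ord), , drop = FALSE]
      return(list(marker_id = hit - 1L, corners = corners))
    }
    cand <- rotate_bits(cand)
  }
  NULL
}

# Sub-pixel corner refinement: locate the black-border/quiet-zone edge
# crossing along normals at points spread over each side, fit a line per
# side, intersect adjacent lines.
refine_corners <- function(m, th, corners) {
  lines <- vector("list", 4)
  for (k in 1:4) {
    a <- corners[k, ]; b <- corners[k %% 4 + 1, ]
    ts <- seq(0.2, 0.8, length.out = 9)
    base <- cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
    e <- b - a
    nvec <- c(-e[2], e[1]) / sqrt(sum(e^2))   # outward for clockwise quads
    pts <- matrix(NA_real_, 0, 2)
    for (i in seq_len(nrow(base))) {
      cr <- edge_crossing(m, th, base[i, ], nvec)
      if (!is.null(cr)) pts <- rbind(pts, cr)
    }
    if (nrow(pts) < 4) return(corners)        # keep coarse corners
    lines[[k]] <- fit_line(pts)
  }
  refined <- corners
  for (k in 1:4) {
    p <- intersect_lines(lines[[(k - 2) %% 4 + 1]], lines[[k]])
    if (is.null(p) || sqrt(sum((p - corners[k, ])^2)) > 3) return(corners)
    refined[k, ] <- p
  }
  refined
}

# Sub-pixel 50%-threshold crossing along the normal through `p`.
edge_crossing <- function(m, th, p, nvec, span = 2, step = 0.25) {
  ss <- seq(-span, span, by = step)
  q <- cbind(p[1] + ss * nvec[1], p[2] + ss * nvec[2])
  rr <- q[, 2] + 0.5; cc <- q[, 1] + 0.5
  if (any(rr < 1 | rr > nrow(m) | cc < 1 | cc > ncol(m))) return(NULL)
  g <- bilinear_sample(m, rr, cc)
  below <- g < th
  flips <- which(below[-length(below)] != below[-1])   # either direction
  if (!length(flips)) return(NULL)
  i <- flips[which.min(abs(ss[flips] + step / 2))]
  f <- (th - g[i]) / (g[i + 1] - g[i])
  s0 <- ss[i] + f * step
  c(p[1] + s0 * nvec[1], p[2] + s0 * nvec[2])
}

# Total-least-squares line fit; returns list(point, dir).
fit_line <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(point = ctr, dir = sv$v[, 1])
}

intersect_lines <- function(l1, l2) {
  A <- cbind(l1$dir, -l2$dir)
  if (abs(det(A)) < 1e-9) return(NULL)
  st <- solve(A, l2$point - l1$point)
  l1$point + st[1] * l1$dir
}

# --- Planar pose estimation ------------------------------------------------

#' Estimate the camera-frame pose of an observed marker
#'
#' Planar perspective-n-point from the four marker corners: a DLT
#' homography between marker-plane coordinates and normalised image
#' coordinates is decomposed into rotation and translation, then both
#' branches of the planar ambiguity (the second obtained by reflecting the
#' plane normal about the line of sight) are refined by minimising the
#' reprojection error over rotation and translation; the branch with the
#' lower RMS wins.
#'
#' @param observation Observation from [detect_markers()] (or any list
#'   with a 4x2 `$corners` matrix, pattern top-left first, clockwise).
#' @param intrinsics [camera_intrinsics()].
#' @param side Marker side length, metres.
#' @return A [pose()] of the marker in the camera frame with attribute
#'   `reprojection_rms` (pixels).
#' @export
estimate_marker_pose <- function(observation, intrinsics, side) {
  corners <- observation$corners
  stopifnot(is.matrix(corners), all(dim(corners) == c(4, 2)))
  if (abs(polygon_area(corners)) < 1e-6) stop("degenerate marker corners")
  obj <- marker_corners_local(side)[, 1:2]
  # normalised, y-up image coordinates
  xn <- cbind((corners[, 1] - intrinsics$cx) / intrinsics$focal_x,
              -(corners[, 2] - intrinsics$cy) / intrinsics$focal_y)
  H <- homography_dlt(obj, xn)
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  lam <- 2 / (sqrt(sum(h1^2)) + sqrt(sum(h2^2)))
  r1 <- h1 * lam; r2 <- h2 * lam; t <- h3 * lam
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  R0 <- orthonormalise(cbind(r1, r2, pracma_cross(r1, r2)))
  branches <- list(list(R = R0, t = t),
                   list(R = reflect_branch(R0, t), t = t))
  best <- NULL
  for (br in branches) {
    fit <- refine_pnp(obj3 = marker_corners_local(side), corners, intrinsics,
                      br$R, br$t)
    if (is.null(best) || fit$rms < best$rms) best <- fit
  }
  out <- pose(best$t, best$R)
  attr(out, "reprojection_rms") <- best$rms
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

orthonormalise <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  R
}

# Second solution of the planar ambiguity: reflect the plane normal about
# the viewing direction and re-orthonormalise.
reflect_branch <- function(R, t) {
  v <- t / sqrt(sum(t^2))
  n <- R[, 3]
  n2 <- 2 * sum(v * n) * v - n
  axis <- pracma_cross(n, n2)
  na <- sqrt(sum(axis^2))
  if (na < 1e-12) return(R)
  axis <- axis / na
  ang <- acos(pmin(1, pmax(-1, sum(n * n2))))
  axis_angle_matrix(axis * ang) %*% R
}

axis_angle_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

refine_pnp <- function(obj3, corners, intrinsics, R0, t0) {
  reproj <- function(R, t) {
    p <- sweep(obj3 %*% t(R), 2, t, `+`)
    project_camera(intrinsics, p)
  }
  cost <- function(par) {
    R <- axis_angle_matrix(par[1:3]) %*% R0
    t <- par[4:6]
    p <- sweep(obj3 %*% t(R), 2, t, `+`)
    if (any(p[, 3] <= 1e-9)) return(1e12)
    pr <- cbind(intrinsics$cx + intrinsics$focal_x * p[, 1] / p[, 3],
                intrinsics$cy - intrinsics$focal_y * p[, 2] / p[, 3])
    sum((pr - corners)^2)
  }
  fit <- stats::optim(c(0, 0, 0, t0), cost, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  R <- axis_angle_matrix(fit$par[1:3]) %*% R0
  t <- fit$par[4:6]
  list(R = R, t = t, rms = sqrt(fit$value / 4))
}

# --- Marker maps and rig solving -------------------------------------------

#' Marker map: where each marker sits in the rig
#'
#' Each entry attaches one marker either to a named display or to the
#' observer, flush on the attachment plane with the pattern upright (which
#' makes the offset rotation the identity): `offset_m` is the marker
#' centre's in-plane position in the attachment frame.  Display entries
#' carry the physical panel metadata needed to rebuild a [display_spec()].
#'
#' @param markers List of `list(id = , side_m = , attach = <display name
#'   or "observer">, offset_m = c(x, y))`.
#' @param displays List of `list(name = , width_m = , height_m = ,
#'   resolution = c(x, y))`.
#' @return An object of class `marker_map`.
#' @export
marker_map <- function(markers, displays = list()) {
  for (mk in markers) {
    if (is.null(mk$id) || is.null(mk$side_m) || is.null(mk$attach)) {
      stop("each marker needs id, side_m and attach")
    }
    if (mk$side_m <= 0) stop("marker side_m must be positive")
  }
  names(displays) <- vapply(displays, `[[`, "", "name")
  structure(list(markers = markers, displays = displays), class = "marker_map")
}

#' Read / write a marker map (YAML or JSON)
#' @param path File path.
#' @return A [marker_map()] (for the reader).
#' @export
read_marker_map <- function(path) {
  raw <- parse_config_file(path)
  marker_map(raw$markers, raw$displays %||% list())
}

#' @rdname read_marker_map
#' @param map A [marker_map()].
#' @export
write_marker_map <- function(map, path) {
  out <- list(markers = map$markers, displays = unname(map$displays))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 12)
  }
  invisible(path)
}

marker_offset_pose <- function(mk) {
  off <- mk$offset_m %||% c(0, 0)
  pose(position = c(off[1], off[2], 0))
}

#' Recover display and observer geometry from marker observations
#'
#' Each detected marker gives a camera-frame pose; attachment offsets from
#' the marker map turn these into camera-frame poses of their display (or
#' of the observer), multiple markers per attachment are averaged (mean
#' position, chordal-mean quaternion rotation), and everything is
#' re-expressed in the observer frame.  When no observer marker is mapped,
#' the camera optical centre is taken as the observer (the camera frame
#' shares the observer frame's axis convention).
#'
#' @param observations List from [detect_markers()].
#' @param intrinsics [camera_intrinsics()].
#' @param map [marker_map()].
#' @return A `calibration_result`: list with `$rig` (a `rig_config` usable
#'   by [render_display()]), `$markers` (per-marker tibble with
#'   reprojection RMS) and `$observer_from_camera` flag.
#' @export
solve_display_geometry <- function(observations, intrinsics, map) {
  stopifnot(inherits(map, "marker_map"))
  entries <- map$markers
  ids <- vapply(entries, function(e) as.integer(e$id), 0L)
  rows <- list()
  att_poses <- list()
  for (obs in observations) {
    k <- match(obs$marker_id, ids)
    if (is.na(k)) next
    e <- entries[[k]]
    p_cam_marker <- estimate_marker_pose(obs, intrinsics, e$side_m)
    p_cam_att <- transform_pose(p_cam_marker, pose_inverse(marker_offset_pose(e)))
    att <- as.character(e$attach)
    att_poses[[att]] <- c(att_poses[[att]], list(p_cam_att))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      marker_id = obs$marker_id, attach = att,
      reprojection_rms = attr(p_cam_marker, "reprojection_rms")
    )
  }
  display_names <- names(map$displays)
  missing <- setdiff(display_names, names(att_poses))
  if (length(missing)) {
    stop("no markers detected for display(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  avg <- lapply(att_poses, average_poses)
  if ("observer" %in% names(avg)) {
    cam_obs <- avg[["observer"]]
    observer_from_camera <- FALSE
  } else {
    cam_obs <- pose_identity()
    observer_from_camera <- TRUE
  }
  obs_cam <- pose_inverse(cam_obs)
  displays <- lapply(display_names, function(nm) {
    meta <- map$displays[[nm]]
    display_spec(
      name = nm,
      pose = transform_pose(obs_cam, avg[[nm]]),
      width = meta$width_m, height = meta$height_m,
      resolution_x = meta$resolution[1], resolution_y = meta$resolution[2]
    )
  })
  names(displays) <- display_names
  rig <- structure(
    list(observer = observer_spec(), displays = displays),
    class = "rig_config"
  )
  structure(
    list(
      rig = rig,
      markers = dplyr::bind_rows(rows),
      observer_from_camera = observer_from_camera
    ),
    class = "calibration_result"
  )
}

average_poses <- function(poses) {
  pos <- Reduce(`+`, lapply(poses, `[[`, "position")) / length(poses)
  if (length(poses) == 1) return(pose(pos, poses[[1]]$rotation))
  q <- quat_mean(lapply(poses, function(p) quat_from_rotation(p$rotation)))
  pose(pos, rotation_from_quat(q))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>", nrow(x$markers), "markers,",
      length(x$rig$displays), "display(s)\n")
  if (x$observer_from_camera) cat("  observer taken as camera optical centre\n")
  print(x$markers)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_result <- function(x, ...) {
  disp <- purrr::map_dfr(x$rig$displays, function(d) {
    eu <- euler_from_rotation(d$pose$rotation)
    tibble::tibble(
      display = d$name,
      x_m = d$pose$position[1], y_m = d$pose$position[2],
      z_m = d$pose$position[3],
      rx_deg = eu[1], ry_deg = eu[2], rz_deg = eu[3]
    )
  })
  disp
}

#' @exportS3Method generics::glance
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$markers),
    n_displays = length(x$rig$displays),
    mean_reprojection_rms = mean(x$markers$reprojection_rms),
    max_reprojection_rms = max(x$markers$reprojection_rms),
    observer_from_camera = x$observer_from_camera
  )
}
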