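# Rendering pipeline: scene -> observer-centred cube map -> display /
# warp mesh / stereo eyes.  Cube maps are expressed in the observer's head
# frame, so the same map serves any number of displays; each display pixel
# fetches the cube-map texel its view direction points at, which is what
# makes the stimulus definition independent of the display hardware.

#' Render a scene to an observer-centred cube map
#'
#' Casts a ray from the observer position through the direction of every
#' texel of all six cube faces (directions in the observer's head frame,
#' rotated into the world by the observer orientation) and shades it by
#' analytic nearest-hit intersection; misses sample the background.
#'
#' @param scn A [scene()].
#' @param observer An [observer_spec()].
#' @param face_resolution Texels per cube-face edge (>= 4).
#' @param supersample If `TRUE`, 2x2 supersampling per texel (default off;
#'   the reference path is unfiltered).
#' @return A [cube_map()].
#' @export
render_cubemap <- function(scn, observer, face_resolution, supersample = FALSE) {
  if (face_resolution < 4) stop("face_resolution must be >= 4")
  stopifnot(inherits(observer, "observer_spec"))
  Rw <- observer$pose$rotation
  origin <- observer$pose$position
  shade <- function(n, offset_s = 0, offset_t = 0) {
    lapply(CUBE_FACES, function(f) {
      d_head <- cube_face_directions(f, n)
      d_world <- d_head %*% t(Rw)
      matrix(raycast_scene(scn, origin, d_world), nrow = n)
    })
  }
  if (!supersample) {
    faces <- shade(face_resolution)
  } else {
    n2 <- 2L * face_resolution
    fine <- shade(n2)
    faces <- lapply(fine, function(f) {
      # average 2x2 blocks
      (f[seq(1, n2, 2), seq(1, n2, 2)] + f[seq(2, n2, 2), seq(1, n2, 2)] +
         f[seq(1, n2, 2), seq(2, n2, 2)] + f[seq(2, n2, 2), seq(2, n2, 2)]) / 4
    })
  }
  names(faces) <- CUBE_FACES
  cube_map(faces)
}

#' Render a cube map onto a physical display
#'
#' Each output pixel's view direction (from [pixel_to_direction()], i.e.
#' the ray from the observer through that pixel's physical location) is
#' transformed into the observer's head frame and the cube map sampled
#' there.  A display may sit anywhere, including behind the observer.
#'
#' @param map A [cube_map()].
#' @param display A [display_spec()].
#' @param observer An [observer_spec()] in the same frame as the display.
#' @param mode Cube-map sampling mode, `"bilinear"` or `"nearest"`.
#' @return An `rw_image`: a `resolution_y x resolution_x` luminance matrix.
#' @export
render_display <- function(map, display, observer, mode = "bilinear") {
  stopifnot(inherits(map, "cube_map"), inherits(display, "display_spec"),
            inherits(observer, "observer_spec"))
  g <- display_pixel_grid(display)
  d_world <- pixel_to_direction(display, observer, g$u, g$v)
  d_head <- d_world %*% observer$pose$rotation
  vals <- sample_cubemap(map, d_head, mode = mode)
  rw_image(matrix(vals, nrow = g$ny, ncol = g$nx))
}

#' Luminance image
#'
#' Thin wrapper marking a numeric matrix (rows = image rows, top first;
#' values in `[0, 1]`) as a rendered image.
#'
#' @param m Numeric matrix.
#' @return An `rw_image`.
#' @export
rw_image <- function(m) {
  stopifnot(is.matrix(m))
  v <- pmin(1, pmax(0, m))          # pmax() drops dim; restore it
  dim(v) <- dim(m)
  structure(v, class = c("rw_image", "matrix", "array"))
}

#' @export
print.rw_image <- function(x, ...) {
  cat(sprintf("<rw_image> %d x %d px, range [%.3f, %.3f]\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

#' Write an image as 8-bit grayscale PNG
#' @param image An `rw_image` (or plain matrix in `[0, 1]`).
#' @param path Output path.
#' @param bits 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path, bits = 8) {
  m <- unclass(image)
  v <- pmin(1, pmax(0, m))
  dim(v) <- dim(m)
  # quantise explicitly so output depth is under our control
  levels <- 2^bits - 1
  png::writePNG(round(v * levels) / levels, path)
  invisible(path)
}

#' Read a grayscale PNG as an image
#' @param path PNG path.
#' @return An `rw_image` (colour files are averaged to luminance).
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  rw_image(a)
}

# --- Warp meshes -----------------------------------------------------------

#' Projector warp mesh
#'
#' A regular grid over output (projector) pixel coordinates; each node maps
#' to a view direction given as azimuth/elevation, or is flagged invalid.
#' Decoupling the mesh from any dome radius keeps curved-screen rendering a
#' pure direction lookup.
#'
#' @param azimuth,elevation Numeric matrices (grid rows x cols >= 2x2),
#'   degrees; node `[1, 1]` is the top-left of the output.
#' @param valid Logical matrix, same size (default all `TRUE`).
#' @return An object of class `warp_mesh`.
#' @export
warp_mesh <- function(azimuth, elevation, valid = NULL) {
  stopifnot(is.matrix(azimuth), is.matrix(elevation),
            all(dim(azimuth) == dim(elevation)))
  if (nrow(azimuth) < 2 || ncol(azimuth) < 2) stop("mesh grid must be >= 2x2")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(azimuth), ncol(azimuth))
  stopifnot(all(dim(valid) == dim(azimuth)))
  bad <- valid & (!is.finite(azimuth) | !is.finite(elevation))
  if (any(bad)) stop("valid mesh nodes must have finite directions")
  structure(list(azimuth = azimuth, elevation = elevation, valid = valid),
            class = "warp_mesh")
}

#' Read / write a warp mesh as CSV
#'
#' Long format `{u, v, azimuth_deg, elevation_deg, valid}` with `u`, `v`
#' the node position in `[0, 1]` of the output image (one row per node of
#' the regular grid).
#'
#' @param path CSV path.
#' @return A [warp_mesh()] (for `read_warp_mesh`).
#' @export
read_warp_mesh <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  us <- sort(unique(d$u)); vs <- sort(unique(d$v))
  idx <- cbind(match(d$v, vs), match(d$u, us))
  az <- el <- matrix(NA_real_, length(vs), length(us))
  ok <- matrix(FALSE, length(vs), length(us))
  az[idx] <- d$azimuth_deg; el[idx] <- d$elevation_deg
  ok[idx] <- as.logical(d$valid)
  warp_mesh(az, el, ok)
}

#' @rdname read_warp_mesh
#' @param mesh A [warp_mesh()].
#' @export
write_warp_mesh <- function(mesh, path) {
  nr <- nrow(mesh$azimuth); nc <- ncol(mesh$azimuth)
  d <- tibble::tibble(
    u = rep((seq_len(nc) - 1) / (nc - 1), each = nr),
    v = rep((seq_len(nr) - 1) / (nr - 1), times = nc),
    azimuth_deg = as.vector(mesh$azimuth),
    elevation_deg = as.vector(mesh$elevation),
    valid = as.vector(mesh$valid)
  )
  readr::write_csv(d, path)
  invisible(path)
}

#' Render a cube map through a warp mesh
#'
#' For every output pixel the four surrounding mesh nodes are interpolated
#' bilinearly (on direction vectors, then renormalised, so the +/-180
#' azimuth wrap is safe) and the cube map sampled along the result.  Pixels
#' in a cell with any invalid node render black.
#'
#' @param map A [cube_map()].
#' @param mesh A [warp_mesh()].
#' @param width,height Output resolution in pixels.
#' @return An `rw_image`.
#' @export
render_warped <- function(map, mesh, width, height) {
  stopifnot(inherits(map, "cube_map"), inherits(mesh, "warp_mesh"))
  nr <- nrow(mesh$azimuth); nc <- ncol(mesh$azimuth)
  dirs_nodes <- direction_from_spherical(as.vector(mesh$azimuth),
                                         as.vector(mesh$elevation))
  DX <- matrix(dirs_nodes[, 1], nr, nc)
  DY <- matrix(dirs_nodes[, 2], nr, nc)
  DZ <- matrix(dirs_nodes[, 3], nr, nc)
  # pixel centres in mesh grid coordinates (nodes at 1..nc / 1..nr)
  gu <- ((seq_len(width) - 0.5) / width) * (nc - 1) + 1
  gv <- ((seq_len(height) - 0.5) / height) * (nr - 1) + 1
  rr <- rep(gv, times = width)
  cc <- rep(gu, each = height)
  dx <- bilinear_sample(DX, rr, cc)
  dy <- bilinear_sample(DY, rr, cc)
  dz <- bilinear_sample(DZ, rr, cc)
  d <- cbind(dx, dy, dz)
  nrm <- sqrt(rowSums(d^2))
  # cell validity: all four surrounding nodes must be valid
  r0 <- pmin(nr - 1L, pmax(1L, floor(rr))); c0 <- pmin(nc - 1L, pmax(1L, floor(cc)))
  ok <- mesh$valid[cbind(r0, c0)] & mesh$valid[cbind(r0 + 1L, c0)] &
    mesh$valid[cbind(r0, c0 + 1L)] & mesh$valid[cbind(r0 + 1L, c0 + 1L)] &
    nrm > 1e-9
  vals <- numeric(length(ok))
  if (any(ok)) vals[ok] <- sample_cubemap(map, d[ok, , drop = FALSE] / nrm[ok])
  rw_image(matrix(vals, nrow = height, ncol = width))
}

#' Warp mesh equivalent to a flat display
#'
#' Builds the mesh whose nodes reproduce a display's pixel-to-direction
#' field; rendering through it matches [render_display()] up to
#' interpolation.
#'
#' @param display A [display_spec()].
#' @param observer An [observer_spec()].
#' @param nodes_x,nodes_y Mesh grid size.
#' @return A [warp_mesh()].
#' @export
display_warp_mesh <- function(display, observer, nodes_x = 17, nodes_y = 17) {
  u <- rep((seq_len(nodes_x) - 1) / (nodes_x - 1), each = nodes_y)
  v <- rep((seq_len(nodes_y) - 1) / (nodes_y - 1), times = nodes_x)
  d_world <- pixel_to_direction(display, observer, u, v)
  d_head <- d_world %*% observer$pose$rotation
  sph <- spherical_from_direction(d_head)
  warp_mesh(matrix(sph$azimuth, nodes_y, nodes_x),
            matrix(sph$elevation, nodes_y, nodes_x))
}

# --- Stereo ----------------------------------------------------------------

#' Per-eye view and projection matrices
#'
#' The view matrix maps world to eye coordinates with the package
#' convention of +z forward (an OpenGL-style matrix, which looks down -z,
#' converts by negating its third row).  The projection must have the
#' standard symmetric perspective structure; only `P[1,1]` and `P[2,2]`
#' (the cotangents of the half field of view) shape the rays.
#'
#' @param view 4x4 rigid world-to-eye matrix.
#' @param projection 4x4 perspective matrix.
#' @return An object of class `eye_matrices`.
#' @export
eye_matrices <- function(view, projection) {
  stopifnot(is.matrix(view), all(dim(view) == c(4, 4)),
            is.matrix(projection), all(dim(projection) == c(4, 4)))
  if (abs(det(view)) < 1e-12) stop("singular view matrix")
  if (projection[1, 1] == 0 || projection[2, 2] == 0) {
    stop("degenerate projection matrix")
  }
  structure(list(view = view, projection = projection), class = "eye_matrices")
}

#' Build eye matrices from an eye pose and field of view
#'
#' @param eye_pose A [pose()] of the eye (+z = gaze).
#' @param fov_y_deg Vertical field of view, degrees.
#' @param aspect Width / height aspect ratio.
#' @param near,far Clip distances, metres.
#' @return An [eye_matrices()].
#' @export
eye_matrices_from_pose <- function(eye_pose, fov_y_deg = 90, aspect = 1,
                                   near = 0.01, far = 100) {
  inv <- pose_inverse(eye_pose)
  view <- rbind(cbind(inv$rotation, inv$position), c(0, 0, 0, 1))
  f <- 1 / tan(fov_y_deg / 2 * DEG2RAD)
  proj <- matrix(0, 4, 4)
  proj[1, 1] <- f / aspect
  proj[2, 2] <- f
  proj[3, 3] <- (far + near) / (far - near)
  proj[3, 4] <- -2 * far * near / (far - near)
  proj[4, 3] <- 1
  eye_matrices(view, proj)
}

# Eye origin and world ray directions for a pixel grid.
eye_rays <- function(eye, width, height) {
  Vi <- solve(eye$view)
  origin <- Vi[1:3, 4]
  Rwe <- Vi[1:3, 1:3]
  tanx <- 1 / eye$projection[1, 1]
  tany <- 1 / eye$projection[2, 2]
  xn <- (2 * ((seq_len(width) - 0.5) / width) - 1)
  yn <- (1 - 2 * ((seq_len(height) - 0.5) / height))
  de <- cbind(
    rep(xn, each = height) * tanx,
    rep(yn, times = width) * tany,
    1
  )
  list(origin = origin, dirs = de %*% t(Rwe))
}

#' Render a scene for two eyes
#'
#' Raycasts the scene once per eye with the given view/projection
#' matrices.  With identical matrices the two images are identical; a
#' skybox-only scene has zero disparity.
#'
#' @param scn A [scene()].
#' @param left,right [eye_matrices()] per eye.
#' @param width,height Output resolution per eye.
#' @return List with `rw_image`s `$left` and `$right`.
#' @export
render_stereo <- function(scn, left, right, width, height) {
  stopifnot(inherits(left, "eye_matrices"), inherits(right, "eye_matrices"))
  one <- function(eye) {
    r <- eye_rays(eye, width, height)
    rw_image(matrix(raycast_scene(scn, r$origin, r$dirs),
                    nrow = height, ncol = width))
  }
  list(left = one(left), right = one(right))
}

#' Project a world point through eye matrices
#'
#' @param eye An [eye_matrices()].
#' @param point Length-3 world point.
#' @return Named vector `c(x, y)` of normalised device coordinates in
#'   `[-1, 1]` (error if the point is at or behind the eye plane).
#' @export
project_point <- function(eye, point) {
  e <- as.numeric(eye$view %*% c(point, 1))
  if (e[3] <= 0) stop("point is behind the eye")
  c(x = eye$projection[1, 1] * e[1] / e[3],
    y = eye$projection[2, 2] * e[2] / e[3])
}

#' Stereo eye poses for an observer
#'
#' Eyes are displaced `+/- ipd/2` along the observer's local x axis, gaze
#' parallel (no toe-in).
#'
#' @param observer An [observer_spec()] with `interpupillary_distance` set.
#' @return List of two [pose()]s, `$left` and `$right`.
#' @export
stereo_eye_poses <- function(observer) {
  stopifnot(inherits(observer, "observer_spec"))
  off <- observer$interpupillary_distance / 2
  shift <- function(s) {
    transform_pose(observer$pose, pose(position = c(s, 0, 0)))
  }
  list(left = shift(-off), right = shift(off))
}

# --- Sync square -----------------------------------------------------------

#' Stamp the photodiode sync square onto a frame
#'
#' Fills a rectangle with white on even `frame_index` and black on odd
#' (frame 0 is white), leaving every other pixel untouched.  A photodiode
#' over this patch timestamps actual frame flips, since the patch switches
#' between black and white at every screen refresh.
#'
#' @param image An `rw_image` (or matrix).
#' @param frame_index Frame number, >= 0.
#' @param rect Integer vector `c(x, y, width, height)`: top-left pixel
#'   (0-based, x rightward, y downward) and size; must be non-empty and lie
#'   inside the image.
#' @return The stamped `rw_image`.
#' @export
apply_sync_square <- function(image, frame_index, rect) {
  m <- unclass(image)
  rect <- as.integer(round(rect))
  if (length(rect) != 4 || rect[3] < 1 || rect[4] < 1) {
    stop("rect must be c(x, y, width, height) with positive size")
  }
  x0 <- rect[1]; y0 <- rect[2]; w <- rect[3]; h <- rect[4]
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(m) || y0 + h > nrow(m)) {
    stop("sync rect outside image")
  }
  m[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] <- ifelse(frame_index %% 2 == 0, 1, 0)
  rw_image(m)
}
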