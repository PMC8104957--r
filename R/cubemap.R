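# Observer-centred cube maps: six square luminance faces covering the full
# 360 degree surround, sampled by view direction.  Faces are expressed in
# the observer's head frame (+x right, +y up, +z forward at zero
# azimuth/elevation); texel (r, c) of a face has in-face coordinates
# s = 2(c - 1/2)/n - 1 (left to right) and t = 2(r - 1/2)/n - 1 (top to
# bottom).

CUBE_FACES <- c("px", "nx", "py", "ny", "pz", "nz")

#' Construct a cube map from six faces
#'
#' @param faces Named list `px, nx, py, ny, pz, nz` of equal-size square
#'   numeric matrices with values in `[0, 1]`.
#' @return An object of class `cube_map`.
#' @export
cube_map <- function(faces) {
  if (!all(CUBE_FACES %in% names(faces))) {
    stop("faces must be named ", paste(CUBE_FACES, collapse = ", "))
  }
  faces <- faces[CUBE_FACES]
  n <- nrow(faces[[1]])
  ok <- vapply(faces, function(f) {
    is.matrix(f) && nrow(f) == n && ncol(f) == n
  }, TRUE)
  if (!all(ok)) stop("all faces must be square matrices of equal size")
  rng <- range(unlist(lapply(faces, range)))
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) stop("face values must be in [0, 1]")
  structure(list(faces = faces, resolution = n), class = "cube_map")
}

#' Uniform cube map
#' @param face_resolution Texels per face edge.
#' @param value Luminance in `[0, 1]`.
#' @return A [cube_map()].
#' @export
cube_map_uniform <- function(face_resolution, value = 0.5) {
  f <- matrix(value, face_resolution, face_resolution)
  cube_map(stats::setNames(rep(list(f), 6), CUBE_FACES))
}

#' @export
print.cube_map <- function(x, ...) {
  cat(sprintf("<cube_map> 6 faces of %d x %d texels\n",
              x$resolution, x$resolution))
  invisible(x)
}

# Direction of a face point given in-face coordinates s, t in [-1, 1].
face_st_to_direction <- function(face, s, t) {
  switch(face,
    px = cbind( 1, -t, -s),
    nx = cbind(-1, -t,  s),
    py = cbind( s,  1,  t),
    ny = cbind( s, -1, -t),
    pz = cbind( s, -t,  1),
    nz = cbind(-s, -t, -1),
    stop("unknown face ", face)
  )
}

#' Unit view directions of every texel of a cube face
#'
#' @param face One of `"px" "nx" "py" "ny" "pz" "nz"`.
#' @param n Face resolution.
#' @return `n^2 x 3` matrix of unit directions, texels in column-major
#'   order over the face matrix (row index fastest).
#' @export
cube_face_directions <- function(face, n) {
  ct <- (seq_len(n) - 0.5) * 2 / n - 1
  s <- rep(ct, each = n)       # column-major: row fastest, s varies per col
  t <- rep(ct, times = n)
  normalize_rows(face_st_to_direction(face, s, t))
}

# Classify directions into faces and continuous texel coordinates.
# Ties on |component| broken in the fixed order px, nx, py, ny, pz, nz.
direction_to_face_st <- function(d) {
  ax <- abs(d)
  axis <- max.col(ax, ties.method = "first")   # 1 = x, 2 = y, 3 = z
  major <- d[cbind(seq_len(nrow(d)), axis)]
  face_id <- (axis - 1L) * 2L + ifelse(major >= 0, 1L, 2L)
  s <- t <- numeric(nrow(d))
  for (k in seq_along(CUBE_FACES)) {
    i <- face_id == k
    if (!any(i)) next
    x <- d[i, 1]; y <- d[i, 2]; z <- d[i, 3]
    st <- switch(CUBE_FACES[k],
      px = cbind(-z / x, -y / x),
      nx = cbind(-z / x,  y / x),
      py = cbind( x / y,  z / y),
      ny = cbind(-x / y,  z / y),
      pz = cbind( x / z, -y / z),
      nz = cbind( x / z,  y / z)
    )
    s[i] <- st[, 1]; t[i] <- st[, 2]
  }
  list(face = CUBE_FACES[face_id], face_id = face_id, s = s, t = t)
}

#' Sample a cube map along view directions
#'
#' The face is chosen by the largest direction component (ties broken in
#' the fixed order `px, nx, py, ny, pz, nz`); within the face, gnomonic
#' texel coordinates are interpolated bilinearly (clamped at face borders,
#' so seams are continuous within one texel).  `mode = "nearest"` returns
#' stored texel values exactly.
#'
#' @param map A [cube_map()].
#' @param direction Length-3 vector or `n x 3` matrix (need not be unit).
#' @param mode `"bilinear"` (default) or `"nearest"`.
#' @return Numeric vector of luminances.
#' @export
sample_cubemap <- function(map, direction, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "cube_map"))
  d <- as_direction_matrix(direction)
  if (any(rowSums(d^2) < 1e-300)) stop("zero direction vector", call. = FALSE)
  fs <- direction_to_face_st(d)
  n <- map$resolution
  cc <- (fs$s + 1) * n / 2 + 0.5
  rr <- (fs$t + 1) * n / 2 + 0.5
  out <- numeric(nrow(d))
  for (k in seq_along(CUBE_FACES)) {
    i <- fs$face_id == k
    if (!any(i)) next
    f <- map$faces[[k]]
    if (mode == "nearest") {
      ri <- pmin(n, pmax(1L, as.integer(round(rr[i]))))
      ci <- pmin(n, pmax(1L, as.integer(round(cc[i]))))
      out[i] <- f[cbind(ri, ci)]
    } else {
      out[i] <- bilinear_sample(f, rr[i], cc[i])
    }
  }
  out
}

#' Write a cube map as six image files
#'
#' Faces are written as 8-bit grayscale PNGs named
#' `<stem>_px.png`, `<stem>_nx.png`, ... `<stem>_nz.png`.
#'
#' @param map A [cube_map()].
#' @param stem Output path stem.
#' @return The six paths, invisibly.
#' @export
write_cubemap_png <- function(map, stem) {
  paths <- vapply(CUBE_FACES, function(f) {
    p <- paste0(stem, "_", f, ".png")
    png::writePNG(pmin(1, pmax(0, map$faces[[f]])), p)
    p
  }, "")
  invisible(paths)
}
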