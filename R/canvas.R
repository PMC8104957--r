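# Visual-field canvases: 2D luminance images gridded in degrees of visual
# field (azimuth on the horizontal axis, elevation as latitude on the
# vertical axis, linear in both -- the equirectangular chart).  Rows run
# from the highest elevation down (image convention); columns from the
# lowest azimuth rightward.

#' Create a visual-field canvas
#'
#' Allocates a retinocentric luminance image covering
#' `centre +/- span/2` in azimuth and elevation, at `resolution` texels per
#' degree, filled with the background luminance.
#'
#' @param centre_azimuth,centre_elevation Canvas centre, degrees.
#' @param span_azimuth Degrees, in (0, 360].
#' @param span_elevation Degrees, in (0, 180].
#' @param resolution Texels per degree (default 4).
#' @param background Background luminance in `[0, 1]` (default 0.5).
#' @return A `visual_field_canvas`: a numeric matrix of luminances in
#'   `[0, 1]` with the extent stored in attributes.
#' @export
visual_field_canvas <- function(centre_azimuth = 0, centre_elevation = 0,
                                span_azimuth = 120, span_elevation = 120,
                                resolution = 4, background = 0.5) {
  if (span_azimuth <= 0 || span_azimuth > 360) stop("span_azimuth must be in (0, 360]")
  if (span_elevation <= 0 || span_elevation > 180) stop("span_elevation must be in (0, 180]")
  if (background < 0 || background > 1) stop("background must be in [0, 1]")
  if (resolution <= 0) stop("resolution must be positive")
  n_az <- max(1L, as.integer(round(span_azimuth * resolution)))
  n_el <- max(1L, as.integer(round(span_elevation * resolution)))
  m <- matrix(background, nrow = n_el, ncol = n_az)
  structure(
    m,
    class = c("visual_field_canvas", "matrix", "array"),
    centre = c(azimuth = centre_azimuth, elevation = centre_elevation),
    span = c(azimuth = span_azimuth, elevation = span_elevation),
    resolution = resolution,
    background = background
  )
}

canvas_like <- function(canvas, values) {
  attributes(values) <- attributes(canvas)
  values
}

#' @export
print.visual_field_canvas <- function(x, ...) {
  ctr <- attr(x, "centre"); sp <- attr(x, "span")
  cat(sprintf(
    "<visual_field_canvas> %d x %d texels, centre (%g, %g) deg, span (%g x %g) deg, %g texel/deg\n",
    nrow(x), ncol(x), ctr[1], ctr[2], sp[1], sp[2], attr(x, "resolution")
  ))
  invisible(x)
}

# Texel-centre coordinates (degrees).  Column k is at
# az_min + (k - 1/2)/res; row r at el_max - (r - 1/2)/res.
canvas_axes <- function(canvas) {
  ctr <- attr(canvas, "centre"); sp <- attr(canvas, "span")
  res <- attr(canvas, "resolution")
  list(
    azimuth = ctr[[1]] - sp[[1]] / 2 + (seq_len(ncol(canvas)) - 0.5) / res,
    elevation = ctr[[2]] + sp[[2]] / 2 - (seq_len(nrow(canvas)) - 0.5) / res
  )
}

#' Texel-centre coordinates of a canvas
#'
#' @param canvas A [visual_field_canvas()].
#' @return Tibble with one row per texel: `row`, `col`, `azimuth`,
#'   `elevation`, `luminance`.
#' @export
canvas_coordinates <- function(canvas) {
  ax <- canvas_axes(canvas)
  tibble::tibble(
    row = rep(seq_len(nrow(canvas)), times = ncol(canvas)),
    col = rep(seq_len(ncol(canvas)), each = nrow(canvas)),
    azimuth = rep(ax$azimuth, each = nrow(canvas)),
    elevation = rep(ax$elevation, times = ncol(canvas)),
    luminance = as.vector(unclass(canvas))
  )
}

# Signed azimuth offset of `az` from `ref`, folded into (-180, 180].
wrap_azimuth_about <- function(az, ref) {
  d <- (az - ref + 180) %% 360 - 180
  d[d <= -180] <- 180
  d
}

#' Sample a canvas at spherical coordinates
#'
#' Bilinear interpolation between texel centres inside the canvas extent
#' (clamped within half a texel of the border); queries outside the extent
#' return the background.  `mode = "nearest"` returns the stored value of
#' the nearest texel, bit-exact, for tests.
#'
#' @param canvas A [visual_field_canvas()].
#' @param azimuth,elevation Query coordinates, degrees (vectorised;
#'   azimuth is folded into the canvas chart across the +/-180 wrap).
#' @param mode `"bilinear"` (default) or `"nearest"`.
#' @return Numeric vector of luminances.
#' @export
sample_canvas <- function(canvas, azimuth, elevation,
                          mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  ctr <- attr(canvas, "centre"); sp <- attr(canvas, "span")
  res <- attr(canvas, "resolution"); bg <- attr(canvas, "background")
  n <- max(length(azimuth), length(elevation))
  az <- rep_len(as.numeric(azimuth), n)
  el <- rep_len(as.numeric(elevation), n)
  daz <- wrap_azimuth_about(az, ctr[[1]])
  del <- el - ctr[[2]]
  inside <- abs(daz) <= sp[[1]] / 2 & abs(del) <= sp[[2]] / 2
  out <- rep(bg, n)
  if (!any(inside)) return(out)
  # continuous texel coordinates (1-based, texel centres at integers)
  cc <- (daz[inside] + sp[[1]] / 2) * res + 0.5
  rr <- (sp[[2]] / 2 - del[inside]) * res + 0.5
  vals <- unclass(canvas)
  if (mode == "nearest") {
    ci <- pmin(ncol(canvas), pmax(1L, as.integer(round(cc))))
    ri <- pmin(nrow(canvas), pmax(1L, as.integer(round(rr))))
    out[inside] <- vals[cbind(ri, ci)]
  } else {
    out[inside] <- bilinear_sample(vals, rr, cc)
  }
  out
}

# Bilinear interpolation on a matrix at continuous (row, col) positions,
# clamped to the border texels.
bilinear_sample <- function(m, rr, cc) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- pmin(nr, pmax(1, rr))
  cc <- pmin(nc, pmax(1, cc))
  r0 <- pmin(nr - 1L, pmax(1L, floor(rr))); r1 <- r0 + ifelse(nr > 1, 1L, 0L)
  c0 <- pmin(nc - 1L, pmax(1L, floor(cc))); c1 <- c0 + ifelse(nc > 1, 1L, 0L)
  fr <- rr - r0; fc <- cc - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc +
    m[cbind(r1, c1)] * fr * fc
}

#' Resample a cube map (or rendered image) back onto a canvas
#'
#' Evaluates the direction of every texel of `canvas` and samples `map`
#' there.  Used to compare renderings from different display geometries in
#' a common visual-angle space.
#'
#' @param map A [cube_map()].
#' @param canvas A [visual_field_canvas()] providing the target grid.
#' @return A new canvas with the sampled luminances.
#' @export
cubemap_to_canvas <- function(map, canvas) {
  co <- canvas_coordinates(canvas)
  d <- direction_from_spherical(co$azimuth, co$elevation)
  vals <- sample_cubemap(map, d)
  canvas_like(canvas, matrix(vals, nrow = nrow(canvas)))
}

#' Project a canvas onto an observer-centred cube map
#'
#' Every texel of each cube face is converted to its view direction, the
#' direction to spherical coordinates, and the canvas sampled there
#' (bilinear); directions outside the canvas extent receive the canvas
#' background.
#'
#' @param canvas A [visual_field_canvas()].
#' @param face_resolution Texels per cube-face edge (>= 4).
#' @return A [cube_map()].
#' @export
canvas_to_cubemap <- function(canvas, face_resolution) {
  if (face_resolution < 4) stop("face_resolution must be >= 4")
  faces <- lapply(CUBE_FACES, function(f) {
    d <- cube_face_directions(f, face_resolution)
    sph <- spherical_from_direction(d)
    matrix(sample_canvas(canvas, sph$azimuth, sph$elevation),
           nrow = face_resolution)
  })
  names(faces) <- CUBE_FACES
  cube_map(faces)
}
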