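# 2D stimulus specifications in retinocentric degrees, rasterised onto a
# visual-field canvas.  Gratings and checkerboards are defined on the
# (azimuth, elevation) chart relative to the canvas centre, so a stated
# spatial frequency holds exactly along the equator of the chart; dots use
# great-circle distance so a 5 degree dot subtends 5 degrees anywhere.

#' Grating stimulus specification
#'
#' Luminance profile
#' `L = mean (1 + contrast * sin(2 pi f (a cos(theta) + e sin(theta)) + phase))`
#' where `(a, e)` are chart coordinates in degrees relative to the canvas
#' centre, clipped to `[0, 1]`.  `square_wave = TRUE` takes the sign of the
#' sinusoid instead.
#'
#' @param spatial_frequency Cycles per degree, > 0.
#' @param orientation Degrees; 0 modulates along azimuth.
#' @param phase Degrees.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param mean_luminance Mean luminance in `[0, 1]`.
#' @param square_wave Square-wave flag.
#' @return A `stimulus_spec` of kind `"grating"`.
#' @export
grating_spec <- function(spatial_frequency, orientation = 0, phase = 0,
                         contrast = 1, mean_luminance = 0.5,
                         square_wave = FALSE) {
  if (spatial_frequency <= 0) stop("spatial_frequency must be > 0")
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  if (mean_luminance < 0 || mean_luminance > 1) stop("mean_luminance must be in [0, 1]")
  structure(
    list(
      kind = "grating", spatial_frequency = spatial_frequency,
      orientation = orientation, phase = phase, contrast = contrast,
      mean_luminance = mean_luminance, square_wave = isTRUE(square_wave)
    ),
    class = "stimulus_spec"
  )
}

#' Checkerboard stimulus specification
#'
#' Checks of `check_size` degrees on the chart, with parity taken relative
#' to the canvas centre: the check containing the centre (offsets in
#' `[0, check_size)`) is white.
#'
#' @param check_size Check side, degrees, > 0.
#' @param luminances Length-2 `c(black, white)` in `[0, 1]`.
#' @return A `stimulus_spec` of kind `"checkerboard"`.
#' @export
checkerboard_spec <- function(check_size, luminances = c(0, 1)) {
  if (check_size <= 0) stop("check_size must be > 0")
  if (any(luminances < 0 | luminances > 1)) stop("luminances must be in [0, 1]")
  structure(
    list(kind = "checkerboard", check_size = check_size, luminances = luminances),
    class = "stimulus_spec"
  )
}

#' Dot stimulus specification
#'
#' A disc of the given angular diameter: texels whose great-circle distance
#' to the centre is below `diameter / 2` are set to the polarity value
#' (black 0, white 1).
#'
#' @param centre_azimuth,centre_elevation Dot centre, degrees.
#' @param diameter Angular diameter, degrees, > 0.
#' @param polarity `"black"` or `"white"`.
#' @return A `stimulus_spec` of kind `"dot"`.
#' @export
dot_spec <- function(centre_azimuth, centre_elevation, diameter,
                     polarity = c("black", "white")) {
  polarity <- match.arg(polarity)
  if (diameter <= 0) stop("diameter must be > 0")
  structure(
    list(
      kind = "dot", centre_azimuth = centre_azimuth,
      centre_elevation = centre_elevation, diameter = diameter,
      polarity = polarity
    ),
    class = "stimulus_spec"
  )
}

#' Rasterise a 2D stimulus onto a canvas
#'
#' Evaluates the stimulus at every texel centre of `canvas` and returns a
#' new canvas (the input is not modified).  A dot whose centre lies outside
#' the canvas extent raises a warning and is clipped.
#'
#' @param canvas A [visual_field_canvas()].
#' @param spec A `stimulus_spec` from [grating_spec()],
#'   [checkerboard_spec()] or [dot_spec()].
#' @return A `visual_field_canvas` with the stimulus drawn.
#' @export
rasterize_stimulus <- function(canvas, spec) {
  stopifnot(inherits(canvas, "visual_field_canvas"),
            inherits(spec, "stimulus_spec"))
  ax <- canvas_axes(canvas)
  ctr <- attr(canvas, "centre")
  a <- wrap_azimuth_about(ax$azimuth, ctr[[1]])   # chart offsets from centre
  e <- ax$elevation - ctr[[2]]
  A <- matrix(a, nrow = nrow(canvas), ncol = ncol(canvas), byrow = TRUE)
  E <- matrix(e, nrow = nrow(canvas), ncol = ncol(canvas))
  vals <- unclass(canvas)
  if (spec$kind == "grating") {
    th <- spec$orientation * DEG2RAD
    arg <- 2 * pi * spec$spatial_frequency * (A * cos(th) + E * sin(th)) +
      spec$phase * DEG2RAD
    mod <- if (spec$square_wave) sign(sin(arg)) else sin(arg)
    vals <- spec$mean_luminance * (1 + spec$contrast * mod)
  } else if (spec$kind == "checkerboard") {
    parity <- (floor(A / spec$check_size) + floor(E / spec$check_size)) %% 2
    vals <- ifelse(parity == 0, spec$luminances[2], spec$luminances[1])
  } else if (spec$kind == "dot") {
    sp <- attr(canvas, "span")
    dctr <- wrap_azimuth_about(spec$centre_azimuth, ctr[[1]])
    if (abs(dctr) > sp[[1]] / 2 ||
        abs(spec$centre_elevation - ctr[[2]]) > sp[[2]] / 2) {
      warning("dot centre outside canvas extent; stimulus clipped")
    }
    # great-circle distance needs absolute latitudes, not centre offsets
    Aabs <- matrix(ax$azimuth, nrow = nrow(canvas), ncol = ncol(canvas), byrow = TRUE)
    Eabs <- matrix(ax$elevation, nrow = nrow(canvas), ncol = ncol(canvas))
    gc <- great_circle_deg(Aabs, Eabs, spec$centre_azimuth, spec$centre_elevation)
    inside <- gc < spec$diameter / 2
    vals[inside] <- if (spec$polarity == "white") 1 else 0
  }
  canvas_like(canvas, matrix(pmin(1, pmax(0, vals)), nrow = nrow(canvas)))
}

# Great-circle distance (degrees) between chart points (a1, e1) and
# (a2, e2), all in degrees.
great_circle_deg <- function(a1, e1, a2, e2) {
  a1 <- a1 * DEG2RAD; e1 <- e1 * DEG2RAD
  a2 <- a2 * DEG2RAD; e2 <- e2 * DEG2RAD
  cosd <- sin(e1) * sin(e2) + cos(e1) * cos(e2) * cos(a1 - a2)
  acos(pmin(1, pmax(-1, cosd))) * RAD2DEG
}

# --- Sparse noise ----------------------------------------------------------

#' Sparse-noise stimulus specification
#'
#' Brief single black or white squares at random grid locations, the
#' classical receptive-field mapping stimulus: each presentation shows one
#' square for `presentation_duration` seconds (default 0.1 s) at a grid
#' location drawn uniformly with replacement, with polarity drawn uniformly
#' from `polarities`.  The whole sequence is reproducible from `seed`.
#'
#' @param grid_rows,grid_cols Grid dimensions, positive integers.
#' @param square_size Side of each square, degrees; must not exceed the
#'   grid cell pitch so squares fit inside the field extent.
#' @param centre_azimuth,centre_elevation,span_azimuth,span_elevation,resolution,background
#'   Field extent and rasterisation parameters, as for
#'   [visual_field_canvas()].
#' @param presentation_duration Seconds per presentation, > 0.
#' @param polarities Subset of `c("black", "white")`.
#' @param seed Integer seed for the presentation sequence.
#' @return A `sparse_noise_spec`.
#' @export
sparse_noise_spec <- function(grid_rows, grid_cols, square_size,
                              centre_azimuth = 0, centre_elevation = 0,
                              span_azimuth = 120, span_elevation = 120,
                              resolution = 4, background = 0.5,
                              presentation_duration = 0.1,
                              polarities = c("black", "white"),
                              seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) stop("grid must be at least 1 x 1")
  if (presentation_duration <= 0) stop("presentation_duration must be > 0")
  polarities <- match.arg(polarities, several.ok = TRUE)
  pitch_az <- span_azimuth / grid_cols
  pitch_el <- span_elevation / grid_rows
  if (square_size <= 0 || square_size > min(pitch_az, pitch_el)) {
    stop("square_size must be positive and fit within one grid cell")
  }
  structure(
    list(
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
      square_size = square_size,
      centre_azimuth = centre_azimuth, centre_elevation = centre_elevation,
      span_azimuth = span_azimuth, span_elevation = span_elevation,
      resolution = resolution, background = background,
      presentation_duration = presentation_duration,
      polarities = polarities, seed = as.integer(seed)
    ),
    class = "sparse_noise_spec"
  )
}

#' Sparse-noise presentation log
#'
#' Draws the first `n_presentations` presentations of the sequence defined
#' by `spec` (independent uniform draws of location and polarity; the same
#' spec always yields the same log).
#'
#' @param spec A [sparse_noise_spec()].
#' @param n_presentations Number of presentations.
#' @return Tibble `{frame, onset_s, row, col, polarity}` with
#'   `onset_s = frame * presentation_duration` (frames count from 0).
#' @export
sparse_noise_log <- function(spec, n_presentations) {
  stopifnot(inherits(spec, "sparse_noise_spec"), n_presentations >= 1)
  # deterministic draw without touching the caller's RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed)
  n <- n_presentations
  tibble::tibble(
    frame = seq_len(n) - 1L,
    onset_s = (seq_len(n) - 1L) * spec$presentation_duration,
    row = sample.int(spec$grid_rows, n, replace = TRUE),
    col = sample.int(spec$grid_cols, n, replace = TRUE),
    polarity = sample(spec$polarities, n, replace = TRUE)
  )
}

# Chart-coordinate centre of a sparse-noise grid cell (degrees, absolute).
sparse_noise_cell_centre <- function(spec, row, col) {
  az_min <- spec$centre_azimuth - spec$span_azimuth / 2
  el_max <- spec$centre_elevation + spec$span_elevation / 2
  list(
    azimuth = az_min + (col - 0.5) * spec$span_azimuth / spec$grid_cols,
    elevation = el_max - (row - 0.5) * spec$span_elevation / spec$grid_rows
  )
}

#' Rasterise one sparse-noise presentation
#'
#' Returns the canvas for `frame_index` (exactly one square on the
#' background) together with its presentation record.  Squares are
#' axis-aligned chart rectangles of side `square_size` centred on the grid
#' cell.
#'
#' @param spec A [sparse_noise_spec()].
#' @param frame_index Presentation index, >= 0.
#' @return List with `$canvas` (a [visual_field_canvas()]) and `$record`
#'   (one-row tibble as in [sparse_noise_log()]).
#' @export
sparse_noise_frame <- function(spec, frame_index) {
  stopifnot(frame_index >= 0)
  log <- sparse_noise_log(spec, frame_index + 1)
  rec <- log[nrow(log), ]
  canvas <- visual_field_canvas(
    spec$centre_azimuth, spec$centre_elevation,
    spec$span_azimuth, spec$span_elevation,
    spec$resolution, spec$background
  )
  ctr <- sparse_noise_cell_centre(spec, rec$row, rec$col)
  ax <- canvas_axes(canvas)
  half <- spec$square_size / 2
  in_az <- abs(wrap_azimuth_about(ax$azimuth, ctr$azimuth)) < half
  in_el <- abs(ax$elevation - ctr$elevation) < half
  vals <- unclass(canvas)
  vals[in_el, in_az] <- if (rec$polarity == "white") 1 else 0
  list(canvas = canvas_like(canvas, vals), record = rec)
}

#' Write a sparse-noise presentation log to CSV
#'
#' @param log Tibble from [sparse_noise_log()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sparse_noise_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}
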