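# Workflow runners behind the command-line interface: render a configured
# stimulus sequence, calibrate a rig from a photo, and generate seeded
# fixtures.  All are plain functions so tests exercise them headlessly.

#' Read an experiment configuration (YAML/JSON)
#'
#' Fields: `rig` (inline rig block or path to a rig file), `canvas`
#' (`centre_azimuth`, `centre_elevation`, `span_azimuth`, `span_elevation`,
#' `resolution`, `background`), `stimulus` (`kind` = grating /
#' checkerboard / dot plus the matching parameters; for gratings
#' `phase_step_deg_per_frame` animates drift), `face_resolution`,
#' `sync_square` (`[x, y, w, h]`, optional), `frame_rate_hz`, `seed`.
#'
#' @param path Config path.
#' @return Validated list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- parse_config_file(path)
  if (is.null(raw$rig)) stop(path, ": missing field 'rig'", call. = FALSE)
  rig <- if (is.character(raw$rig)) {
    read_rig_config(file.path(dirname(path), raw$rig))
  } else {
    rig_from_list(raw$rig, context = paste0(path, ":rig"))
  }
  cv <- raw$canvas %||% list()
  canvas <- visual_field_canvas(
    cv$centre_azimuth %||% 0, cv$centre_elevation %||% 0,
    cv$span_azimuth %||% 120, cv$span_elevation %||% 120,
    cv$resolution %||% 4, cv$background %||% 0.5
  )
  st <- raw$stimulus
  if (is.null(st$kind)) stop(path, ": missing field 'stimulus.kind'", call. = FALSE)
  structure(
    list(
      rig = rig, canvas = canvas, stimulus = st,
      face_resolution = raw$face_resolution %||% 128,
      sync_square = if (!is.null(raw$sync_square)) as.integer(unlist(raw$sync_square)),
      frame_rate_hz = raw$frame_rate_hz %||% 60,
      seed = raw$seed %||% 1L
    ),
    class = "experiment_config"
  )
}

stimulus_from_config <- function(st, frame = 0) {
  switch(st$kind,
    grating = grating_spec(
      spatial_frequency = st$spatial_frequency %||% 0.05,
      orientation = st$orientation %||% 0,
      phase = (st$phase %||% 0) + frame * (st$phase_step_deg_per_frame %||% 0),
      contrast = st$contrast %||% 1,
      mean_luminance = st$mean_luminance %||% 0.5,
      square_wave = isTRUE(st$square_wave)
    ),
    checkerboard = checkerboard_spec(st$check_size %||% 10),
    dot = dot_spec(st$centre_azimuth %||% 0, st$centre_elevation %||% 0,
                   st$diameter %||% 5, st$polarity %||% "black"),
    stop("unknown stimulus kind: ", st$kind)
  )
}

#' Render a configured frame sequence to image files
#'
#' Renders `frames` frames of the configured stimulus for every display of
#' the rig, stamps the sync square (before any linearisation LUT a caller
#' may apply, so photodiode contrast stays maximal), writes 8-bit PNGs
#' `<display>_<frame>.png` and a frame-log CSV, all deterministic given
#' the config.
#'
#' @param config An `experiment_config` (or path to one).
#' @param frames Number of frames (>= 1).
#' @param out_dir Output directory (created if needed).
#' @return Tibble frame log `{frame, t_sched_s, t_pres_s, state}`,
#'   invisibly; files as side effects.
#' @export
run_render_job <- function(config, frames, out_dir) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"), frames >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dt <- 1 / config$frame_rate_hz
  log <- vector("list", frames)
  for (f in seq_len(frames) - 1L) {
    spec <- stimulus_from_config(config$stimulus, f)
    canvas <- rasterize_stimulus(config$canvas, spec)
    map <- canvas_to_cubemap(canvas, config$face_resolution)
    for (d in config$rig$displays) {
      img <- render_display(map, d, config$rig$observer)
      if (!is.null(config$sync_square)) {
        img <- apply_sync_square(img, f, config$sync_square)
      }
      write_image_png(img, file.path(out_dir, sprintf("%s_%04d.png", d$name, f)))
    }
    log[[f + 1L]] <- tibble::tibble(
      frame = f, t_sched_s = f * dt, t_pres_s = f * dt,
      state = paste0(config$stimulus$kind, "_", f)
    )
  }
  log <- dplyr::bind_rows(log)
  write_frame_log(log, file.path(out_dir, "frame_log.csv"))
  invisible(log)
}

#' Read camera intrinsics from YAML/JSON
#' @param path File with `focal_x`, `focal_y`, `cx`, `cy` (pixels).
#' @return A [camera_intrinsics()].
#' @export
read_camera_intrinsics <- function(path) {
  raw <- parse_config_file(path)
  camera_intrinsics(raw$focal_x, raw$focal_y %||% raw$focal_x, raw$cx, raw$cy)
}

#' Calibrate a rig from a marker photograph
#'
#' Detects markers in the photo, solves the display geometry, and writes
#' the recovered rig as a config file directly usable by
#' [run_render_job()].  Errors (with no file written) if the photo
#' contains no detectable markers.
#'
#' @param photo_path Grayscale PNG of the rig with fiducial markers.
#' @param intrinsics_path Camera intrinsics file.
#' @param marker_map_path Marker map file.
#' @param out_path Output rig config path (`.yml` or `.json`).
#' @return The [solve_display_geometry()] result, invisibly.
#' @export
run_calibration_job <- function(photo_path, intrinsics_path, marker_map_path,
                                out_path) {
  photo <- read_image_png(photo_path)
  intr <- read_camera_intrinsics(intrinsics_path)
  map <- read_marker_map(marker_map_path)
  obs <- detect_markers(photo)
  if (!length(obs)) stop("no fiducial markers found in ", photo_path, call. = FALSE)
  result <- solve_display_geometry(obs, intr, map)
  write_rig_config(result$rig, out_path)
  invisible(result)
}

# --- Fixture generation ----------------------------------------------------

#' Generate seeded test fixtures
#'
#' Writes self-describing fixture files for a test surface: synthetic
#' marker photographs with ground-truth poses, synthetic neurons with
#' spike trains, pose streams, speed traces, or frame logs with known
#' drop counts.  Identical seed, identical files.
#'
#' @param kind One of `"marker_photo"`, `"neuron"`, `"pose_stream"`,
#'   `"speed_trace"`, `"frame_log"`.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
make_fixtures <- function(kind, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  switch(kind,
    marker_photo = fixture_marker_photo(out_dir),
    neuron = fixture_neuron(seed, out_dir),
    pose_stream = fixture_pose_stream(out_dir),
    speed_trace = fixture_speed_trace(out_dir),
    frame_log = fixture_frame_log(out_dir),
    stop("unknown fixture kind: ", kind)
  )
}

# A one-display rig seen by a camera at the observer position: display
# marker at the panel centre, observer marker taken as the camera.
fixture_marker_photo <- function(out_dir) {
  intr <- camera_intrinsics(800, 800, 480, 360)
  z <- stats::runif(1, 0.4, 0.7)
  yaw <- stats::runif(1, -20, 20)
  disp_pose <- pose(c(stats::runif(1, -0.1, 0.1), stats::runif(1, -0.05, 0.05), z),
                    rotation_from_euler(ry = yaw))
  marker_pose <- transform_pose(disp_pose, pose_identity())
  photo <- render_marker_photo(
    list(list(id = 3L, side = 0.08, pose = marker_pose)),
    intr, 960, 720
  )
  p_img <- file.path(out_dir, "marker_photo.png")
  write_image_png(photo, p_img)
  p_truth <- file.path(out_dir, "marker_photo_truth.json")
  eu <- euler_from_rotation(disp_pose$rotation)
  jsonlite::write_json(
    list(
      synthetic = TRUE, marker_id = 3, side_m = 0.08,
      display = list(position_m = disp_pose$position,
                     rotation_deg = as.numeric(eu),
                     width_m = 0.4, height_m = 0.3, resolution = c(640, 480)),
      intrinsics = list(focal_x = 800, focal_y = 800, cx = 480, cy = 360)
    ),
    p_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  p_intr <- file.path(out_dir, "intrinsics.json")
  jsonlite::write_json(list(focal_x = 800, focal_y = 800, cx = 480, cy = 360),
                       p_intr, auto_unbox = TRUE, digits = NA)
  p_map <- file.path(out_dir, "marker_map.yml")
  write_marker_map(marker_map(
    markers = list(list(id = 3, side_m = 0.08, attach = "main",
                        offset_m = c(0, 0))),
    displays = list(list(name = "main", width_m = 0.4, height_m = 0.3,
                         resolution = c(640, 480)))
  ), p_map)
  c(p_img, p_truth, p_intr, p_map)
}

fixture_neuron <- function(seed, out_dir) {
  sn <- sparse_noise_spec(12, 12, 8, span_azimuth = 120, span_elevation = 120,
                          seed = seed)
  log <- sparse_noise_log(sn, 2000)
  spec <- synthetic_neuron_spec(
    centre_row = sample.int(12, 1), centre_col = sample.int(12, 1),
    gain_hz = 50, baseline_hz = 2, seed = seed
  )
  spikes <- simulate_sparse_noise_neuron(spec, log)
  p_spk <- file.path(out_dir, "neuron_spikes.csv")
  write_spike_csv(spikes, p_spk)
  p_log <- file.path(out_dir, "neuron_presentations.csv")
  write_sparse_noise_log(log, p_log)
  p_truth <- file.path(out_dir, "neuron_truth.json")
  jsonlite::write_json(
    list(synthetic = TRUE, centre_row = spec$centre_row,
         centre_col = spec$centre_col, gain_hz = spec$gain_hz,
         baseline_hz = spec$baseline_hz, latency_s = spec$latency_s,
         seed = seed),
    p_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  c(p_spk, p_log, p_truth)
}

fixture_pose_stream <- function(out_dir) {
  t_s <- seq(0, 5, by = 1 / 40)
  pos <- cbind(0.2 * sin(2 * pi * t_s / 5), 0, 0.1 * cos(2 * pi * t_s / 5))
  p <- file.path(out_dir, "pose_stream.csv")
  write_pose_stream(pose_stream(t_s, pos), p)
  p
}

fixture_speed_trace <- function(out_dir) {
  t_s <- seq(0, 10, by = 1 / 60)
  speed <- 10 + 2 * sin(2 * pi * t_s)
  speed[t_s >= 4 & t_s < 4.5] <- 1          # a freeze-worthy dip
  p <- file.path(out_dir, "speed_trace.csv")
  readr::write_csv(tibble::tibble(t_s = t_s, speed_cm_s = speed), p)
  p
}

fixture_frame_log <- function(out_dir) {
  dt <- 1 / 60
  t <- cumsum(c(0, rep(dt, 299)))
  drop_at <- sort(sample(50:250, 3))
  for (d in drop_at) t[(d + 1):length(t)] <- t[(d + 1):length(t)] + dt
  log <- tibble::tibble(frame = seq_along(t) - 1L, t_sched_s = (seq_along(t) - 1L) * dt,
                        t_pres_s = t, state = "test")
  p <- file.path(out_dir, "frame_log.csv")
  write_frame_log(log, p)
  jsonlite::write_json(list(synthetic = TRUE, n_dropped = length(drop_at),
                            after_frames = drop_at),
                       file.path(out_dir, "frame_log_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  c(p, file.path(out_dir, "frame_log_truth.json"))
}
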