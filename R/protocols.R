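# Closed-loop experiment engines: the virtual linear platform driven by a
# running wheel, augmented-reality window rendering driven by a pose
# stream, the overhead sweeping-dot threat stimulus, the depth-size
# judgement scene, frame-drop accounting, and the freeze/flight
# classifier for defensive behaviour.

#' Wheel displacement from encoder counts
#'
#' `displacement = 2 pi radius counts / counts_per_revolution`, signed.
#'
#' @param encoder_counts Signed encoder counts (vectorised).
#' @param counts_per_revolution Counts per full revolution, > 0.
#' @param radius_cm Wheel radius in cm, > 0 (the head-fixed rig uses a
#'   10 cm polystyrene wheel).
#' @return Displacement in cm.
#' @export
wheel_to_displacement <- function(encoder_counts, counts_per_revolution,
                                  radius_cm = 10) {
  if (counts_per_revolution <= 0) stop("counts_per_revolution must be > 0")
  if (radius_cm <= 0) stop("radius_cm must be > 0")
  2 * pi * radius_cm * encoder_counts / counts_per_revolution
}

# --- Virtual platform ------------------------------------------------------

#' Virtual platform specification
#'
#' A linear virtual platform the animal runs along: each trial starts at
#' position 0 and ends on reaching the far end or on timeout, followed by
#' a grey inter-trial interval.
#'
#' @param length_cm Platform length (default 100 cm).
#' @param timeout_s Trial timeout (default 60 s).
#' @param inter_trial_interval_s Grey interval between trials (default 2 s).
#' @return A `virtual_platform_spec`.
#' @export
virtual_platform_spec <- function(length_cm = 100, timeout_s = 60,
                                  inter_trial_interval_s = 2) {
  if (length_cm <= 0 || timeout_s <= 0 || inter_trial_interval_s <= 0) {
    stop("all platform parameters must be positive")
  }
  structure(
    list(length_cm = length_cm, timeout_s = timeout_s,
         inter_trial_interval_s = inter_trial_interval_s),
    class = "virtual_platform_spec"
  )
}

#' Initial platform state
#' @return A `platform_state` in the running phase of trial 1 at position 0.
#' @export
platform_state_init <- function() {
  structure(
    list(phase = "running", position_cm = 0, trial_index = 1L,
         trial_clock_s = 0, time_s = 0),
    class = "platform_state"
  )
}

#' Advance the virtual platform by one time step
#'
#' In the running phase the position advances by `displacement_cm`
#' (clamped at 0: backward running below the start is ignored) and the
#' trial ends when the position reaches the platform length or the trial
#' clock reaches the timeout.  A trial end switches to the grey phase for
#' the inter-trial interval, after which the next trial starts at
#' position 0.
#'
#' @param state A `platform_state` (see [platform_state_init()]).
#' @param displacement_cm Wheel displacement during this step, cm.
#' @param dt_s Step duration, s, > 0.
#' @param spec A [virtual_platform_spec()].
#' @return List `$state` (new state) and `$events` (tibble
#'   `{time_s, trial_index, event, position_cm}`; zero rows if nothing
#'   happened; `event` is `"trial_end"` or `"trial_start"`).
#' @export
step_virtual_platform <- function(state, displacement_cm, dt_s, spec) {
  stopifnot(inherits(state, "platform_state"),
            inherits(spec, "virtual_platform_spec"))
  if (dt_s <= 0) stop("dt_s must be > 0")
  events <- list()
  add_event <- function(ev, pos) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      time_s = state$time_s, trial_index = state$trial_index,
      event = ev, position_cm = pos
    )
  }
  state$time_s <- state$time_s + dt_s
  if (state$phase == "running") {
    state$trial_clock_s <- state$trial_clock_s + dt_s
    state$position_cm <- max(0, state$position_cm + displacement_cm)
    ended_by_distance <- state$position_cm >= spec$length_cm - 1e-9
    ended_by_timeout <- state$trial_clock_s >= spec$timeout_s - 1e-9
    if (ended_by_distance || ended_by_timeout) {
      state$position_cm <- min(state$position_cm, spec$length_cm)
      add_event("trial_end", state$position_cm)
      state$phase <- "grey"
      state$trial_clock_s <- 0
    }
  } else {
    state$trial_clock_s <- state$trial_clock_s + dt_s
    if (state$trial_clock_s >= spec$inter_trial_interval_s - 1e-9) {
      state$phase <- "running"
      state$trial_index <- state$trial_index + 1L
      state$trial_clock_s <- 0
      state$position_cm <- 0
      add_event("trial_start", 0)
    }
  }
  list(state = state,
       events = if (length(events)) dplyr::bind_rows(events)
                else tibble::tibble(time_s = numeric(), trial_index = integer(),
                                    event = character(), position_cm = numeric()))
}

#' Run the virtual platform over a speed trace
#'
#' Convenience driver: steps the platform state machine through a whole
#' uniformly sampled speed trace.
#'
#' @param speed Data frame with `t_s` and `speed_cm_s` (uniform sampling).
#' @param spec A [virtual_platform_spec()].
#' @return List `$trace` (tibble `{t_s, phase, trial_index, position_cm}`)
#'   and `$events` (bound event tibble).
#' @export
run_virtual_platform <- function(speed, spec) {
  ts <- speed$t_s
  dt <- if (length(ts) > 1) stats::median(diff(ts)) else 1 / 60
  st <- platform_state_init()
  rows <- vector("list", length(ts))
  evs <- list()
  for (i in seq_along(ts)) {
    out <- step_virtual_platform(st, speed$speed_cm_s[i] * dt, dt, spec)
    st <- out$state
    if (nrow(out$events)) evs[[length(evs) + 1L]] <- out$events
    rows[[i]] <- tibble::tibble(
      t_s = st$time_s, phase = st$phase,
      trial_index = st$trial_index, position_cm = st$position_cm
    )
  }
  list(trace = dplyr::bind_rows(rows),
       events = if (length(evs)) dplyr::bind_rows(evs)
                else tibble::tibble(time_s = numeric(), trial_index = integer(),
                                    event = character(), position_cm = numeric()))
}

# --- Sweeping dot ----------------------------------------------------------

#' Sweeping-dot specification
#'
#' A small dot appearing on one side of the field and translating linearly
#' to the opposite side (the overhead-threat stimulus: 3.3 s sweep by
#' default).
#'
#' @param start_azimuth,start_elevation Start location, degrees.
#' @param end_azimuth,end_elevation End location, degrees.
#' @param duration_s Sweep duration, s, > 0 (default 3.3).
#' @param diameter_deg Dot diameter, degrees (default 5).
#' @return A `sweep_spec`.
#' @export
sweep_spec <- function(start_azimuth, start_elevation,
                       end_azimuth, end_elevation,
                       duration_s = 3.3, diameter_deg = 5) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (diameter_deg <= 0) stop("diameter_deg must be > 0")
  structure(
    list(start = c(azimuth = start_azimuth, elevation = start_elevation),
         end = c(azimuth = end_azimuth, elevation = end_elevation),
         duration_s = duration_s, diameter_deg = diameter_deg),
    class = "sweep_spec"
  )
}

#' Dot position at a given time of the sweep
#'
#' Linear interpolation between the start and end locations.
#'
#' @param t_s Time since sweep onset, in `[0, duration_s]`.
#' @param spec A [sweep_spec()].
#' @return Tibble `{t_s, azimuth, elevation}` (vectorised over `t_s`).
#' @export
sweeping_dot_position <- function(t_s, spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (any(t_s < 0 | t_s > spec$duration_s)) {
    stop("t_s must lie within [0, duration_s]")
  }
  f <- t_s / spec$duration_s
  tibble::tibble(
    t_s = t_s,
    azimuth = spec$start[["azimuth"]] + f * (spec$end[["azimuth"]] - spec$start[["azimuth"]]),
    elevation = spec$start[["elevation"]] + f * (spec$end[["elevation"]] - spec$start[["elevation"]])
  )
}

# --- Depth-size judgement --------------------------------------------------

#' Scene for a depth-size judgement trial
#'
#' Two cubes at different depths with lateral offsets preventing
#' projection overlap; the observer must rely on depth cues because a cube
#' of size `s` at depth `d` subtends `2 atan(s / 2d)` degrees.
#'
#' @param size_left,size_right Cube sides, metres, > 0.
#' @param depth_left,depth_right Viewing distances, metres, > 0.
#' @param separation_deg Angular separation between the cube centres
#'   (default 30 degrees; placements whose projections would still overlap
#'   are rejected).
#' @return List `$scene` (a [scene()]) and `$angular_sizes` (tibble
#'   `{side, size_m, depth_m, angular_size_deg}`).
#' @export
depth_size_trial_scene <- function(size_left, size_right,
                                   depth_left, depth_right,
                                   separation_deg = 30) {
  if (min(size_left, size_right, depth_left, depth_right) <= 0) {
    stop("sizes and depths must be positive")
  }
  ang <- function(s, d) 2 * atan(s / (2 * d)) * RAD2DEG
  a_l <- ang(size_left, depth_left)
  a_r <- ang(size_right, depth_right)
  if (separation_deg <= (a_l + a_r) / 2) {
    stop("cube projections overlap: increase separation_deg")
  }
  half <- separation_deg / 2 * DEG2RAD
  place <- function(sgn, s, d) {
    ctr <- c(sgn * d * sin(half), 0, d * cos(half))
    scene_object("cube", pose(ctr), scale = s, surface = 0.9)
  }
  list(
    scene = scene(list(place(-1, size_left, depth_left),
                       place(1, size_right, depth_right)),
                  background = 0.2),
    angular_sizes = tibble::tibble(
      side = c("left", "right"),
      size_m = c(size_left, size_right),
      depth_m = c(depth_left, depth_right),
      angular_size_deg = c(a_l, a_r)
    )
  )
}

# --- Augmented-reality windows ---------------------------------------------

#' Interpolate an observer pose stream
#'
#' Linear interpolation of position and spherical-linear interpolation of
#' orientation between bracketing samples.
#'
#' @param stream Tibble with `t_s` (strictly increasing) and `pose`
#'   (list-column of [pose()]s), as produced by [pose_stream()].
#' @param t_s Query time; must lie within the stream span.
#' @return A [pose()].
#' @export
interpolate_pose_stream <- function(stream, t_s) {
  ts <- stream$t_s
  if (!length(ts)) stop("empty pose stream")
  if (t_s < ts[1] || t_s > ts[length(ts)]) {
    stop("query time outside pose stream span")
  }
  i <- findInterval(t_s, ts)
  if (i == length(ts)) return(stream$pose[[i]])
  p0 <- stream$pose[[i]]; p1 <- stream$pose[[i + 1]]
  f <- (t_s - ts[i]) / (ts[i + 1] - ts[i])
  q <- quat_slerp(quat_from_rotation(p0$rotation),
                  quat_from_rotation(p1$rotation), f)
  pose(p0$position * (1 - f) + p1$position * f, rotation_from_quat(q))
}

#' Build a pose stream
#'
#' @param t_s Strictly increasing times, s.
#' @param positions `n x 3` matrix of positions, metres.
#' @param rotations List of rotation matrices (default: identity for all).
#' @return Tibble `{t_s, pose}` with a `pose` list-column.
#' @export
pose_stream <- function(t_s, positions, rotations = NULL) {
  if (any(diff(t_s) <= 0)) stop("pose stream times must be strictly increasing")
  positions <- as_direction_matrix(positions)
  stopifnot(nrow(positions) == length(t_s))
  if (is.null(rotations)) rotations <- rep(list(diag(3)), length(t_s))
  tibble::tibble(
    t_s = t_s,
    pose = purrr::map2(seq_along(t_s), rotations,
                       function(i, R) pose(positions[i, ], R))
  )
}

#' Read / write a pose stream CSV
#'
#' Columns `{t_s, x_m, y_m, z_m, rx_deg, ry_deg, rz_deg}` (rotations
#' optional, default 0).
#' @param path CSV path.
#' @return A pose-stream tibble (for the reader).
#' @export
read_pose_stream <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  rots <- if (!is.null(d$rx_deg)) {
    purrr::pmap(list(d$rx_deg, d$ry_deg, d$rz_deg), rotation_from_euler)
  } else NULL
  pose_stream(d$t_s, cbind(d$x_m, d$y_m, d$z_m), rots)
}

#' @rdname read_pose_stream
#' @param stream Pose-stream tibble.
#' @export
write_pose_stream <- function(stream, path) {
  rows <- purrr::map2_dfr(stream$t_s, stream$pose, function(t, p) {
    eu <- euler_from_rotation(p$rotation)
    tibble::tibble(t_s = t, x_m = p$position[1], y_m = p$position[2],
                   z_m = p$position[3], rx_deg = eu[1], ry_deg = eu[2],
                   rz_deg = eu[3])
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' Render augmented-reality windows at a moment of a pose stream
#'
#' Fixed displays act as windows from a box into a virtual world outside:
#' the observer pose is interpolated at `t_s`, the scene re-rendered to a
#' cube map centred on that pose, and every display rendered as a window.
#' With a constant stream this reduces exactly to a static
#' [render_display()].
#'
#' @param scn A [scene()].
#' @param displays List of [display_spec()]s.
#' @param stream Pose stream tibble (see [pose_stream()]).
#' @param t_s Query time within the stream span.
#' @param face_resolution Cube-map face resolution (default 128).
#' @return Named list of `rw_image`s, one per display.
#' @export
ar_window_render <- function(scn, displays, stream, t_s,
                             face_resolution = 128) {
  if (!nrow(stream)) stop("empty pose stream")
  p <- interpolate_pose_stream(stream, t_s)
  obs <- observer_spec(pose = p)
  map <- render_cubemap(scn, obs, face_resolution)
  out <- lapply(displays, render_display, map = map, observer = obs)
  names(out) <- vapply(displays, `[[`, "", "name")
  out
}

# --- Frame accounting ------------------------------------------------------

#' Detect dropped frames in a presentation log
#'
#' A drop is declared when the gap between consecutive presented frames
#' exceeds 1.5 x the nominal interval; a gap of about `k + 1` intervals
#' counts as `k` dropped frames (`round(gap / nominal) - 1`).
#'
#' @param log Data frame with `frame` (strictly increasing indices) and
#'   `t_pres_s` (presented times); at least 2 records.
#' @param nominal_interval_s Nominal frame interval, s, > 0.
#' @return List `$count` (total dropped frames) and `$gaps` (tibble
#'   `{after_frame, gap_s, n_dropped}` for each offending gap).
#' @export
detect_dropped_frames <- function(log, nominal_interval_s) {
  if (nominal_interval_s <= 0) stop("nominal_interval_s must be > 0")
  if (is.null(log$t_pres_s) || length(log$t_pres_s) < 2) {
    stop("need at least 2 frame records")
  }
  if (!is.null(log$frame) && any(diff(log$frame) <= 0)) {
    stop("frame indices must be strictly increasing")
  }
  gaps <- diff(log$t_pres_s)
  bad <- which(gaps > 1.5 * nominal_interval_s)
  n_drop <- pmax(1L, as.integer(round(gaps[bad] / nominal_interval_s)) - 1L)
  list(
    count = sum(n_drop),
    gaps = tibble::tibble(
      after_frame = if (!is.null(log$frame)) log$frame[bad] else bad,
      gap_s = gaps[bad],
      n_dropped = n_drop
    )
  )
}

#' Write / read a frame log CSV
#'
#' Columns `{frame, t_sched_s, t_pres_s, state}`.
#' @param path CSV path.
#' @return Tibble (for the reader).
#' @export
read_frame_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_frame_log
#' @param log Frame-log tibble.
#' @export
write_frame_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

# --- Defensive behaviour ---------------------------------------------------

#' Classify freeze and flight responses from a speed trace
#'
#' Freezing is a drop of the animal speed below 2 cm/s lasting more than
#' 0.1 s; a flight response is an increase of running speed above
#' 40 cm/s.  Responses only count if they begin within 3.5 s of stimulus
#' onset.  Event times are the interval start (freeze) or the first
#' crossing (flight).
#'
#' @param trace Data frame with `t_s` (uniform sampling) and `speed_cm_s`
#'   (>= 0).
#' @param stimulus_onset_s Onset time, within the trace span.
#' @param freeze_speed_cm_s,freeze_min_duration_s,flight_speed_cm_s,response_window_s
#'   Thresholds; defaults 2 cm/s, 0.1 s, 40 cm/s and 3.5 s.
#' @return Tibble `{type, time_s, latency_s, duration_s}` (freeze
#'   durations; flight duration is `NA`), ordered by time.
#' @export
classify_defensive_behaviour <- function(trace, stimulus_onset_s,
                                         freeze_speed_cm_s = 2,
                                         freeze_min_duration_s = 0.1,
                                         flight_speed_cm_s = 40,
                                         response_window_s = 3.5) {
  ts <- trace$t_s; sp <- trace$speed_cm_s
  if (is.null(ts) || is.null(sp) || !length(ts)) stop("empty speed trace")
  if (stimulus_onset_s < ts[1] || stimulus_onset_s > ts[length(ts)]) {
    stop("stimulus onset outside the trace")
  }
  dt <- if (length(ts) > 1) stats::median(diff(ts)) else 0
  events <- list()
  # freezes: maximal runs below threshold, strictly longer than minimum
  below <- sp < freeze_speed_cm_s
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    dur <- (r$lengths[k] - 1) * dt
    t0 <- ts[starts[k]]
    if (dur > freeze_min_duration_s &&
        t0 >= stimulus_onset_s && t0 - stimulus_onset_s <= response_window_s) {
      events[[length(events) + 1L]] <- tibble::tibble(
        type = "freeze", time_s = t0, latency_s = t0 - stimulus_onset_s,
        duration_s = dur
      )
    }
  }
  # flight: first upward crossing above threshold
  above <- sp > flight_speed_cm_s
  cross <- which(above & !c(FALSE, above[-length(above)]))
  cross <- cross[ts[cross] >= stimulus_onset_s &
                   ts[cross] - stimulus_onset_s <= response_window_s]
  if (length(cross)) {
    t0 <- ts[cross[1]]
    events[[length(events) + 1L]] <- tibble::tibble(
      type = "flight", time_s = t0, latency_s = t0 - stimulus_onset_s,
      duration_s = NA_real_
    )
  }
  if (!length(events)) {
    return(tibble::tibble(type = character(), time_s = numeric(),
                          latency_s = numeric(), duration_s = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(events), .data$time_s)
}

#' Cumulative response-probability curve
#'
#' Fraction of trials with a response of the given type at or before each
#' latency; non-decreasing in time by construction.
#'
#' @param events Tibble of per-trial classifier outputs bound together,
#'   with a `trial` column identifying the trial and `latency_s`.
#' @param type `"freeze"` or `"flight"`.
#' @param n_trials Total number of trials (denominator).
#' @param times Latencies at which to evaluate, s.
#' @return Tibble `{latency_s, cumulative_probability}`.
#' @export
cumulative_response_curve <- function(events, type, n_trials,
                                      times = seq(0, 3.5, by = 0.1)) {
  ev <- dplyr::filter(events, .data$type == !!type)
  first <- dplyr::summarise(dplyr::group_by(ev, .data$trial),
                            latency_s = min(.data$latency_s), .groups = "drop")
  tibble::tibble(
    latency_s = times,
    cumulative_probability = vapply(
      times, function(tt) sum(first$latency_s <= tt) / n_trials, 0
    )
  )
}
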