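# Rig configuration files: one observer block plus a list of display
# blocks.  YAML or JSON, decided by file extension (.yml/.yaml/.json).
#
# observer:
#   position_m: [0, 0, 0]
#   rotation_deg: [0, 0, 0]
#   interpupillary_distance_m: 0.0   # optional
# displays:
#   - name: left
#     position_m: [x, y, z]
#     rotation_deg: [rx, ry, rz]     # applied Rz * Ry * Rx
#     width_m: 0.5
#     height_m: 0.3
#     resolution: [1920, 1080]

#' Read a rig configuration file
#'
#' Loads the observer and display geometry of an experimental rig from a
#' YAML or JSON file and validates it.  Malformed files produce errors that
#' name the offending field.
#'
#' @param path Path to a `.yml`/`.yaml`/`.json` rig file.
#' @return A list with class `rig_config`: `$observer` (an
#'   [observer_spec()]) and `$displays` (named list of [display_spec()]).
#' @export
read_rig_config <- function(path) {
  if (!file.exists(path)) stop("rig config not found: ", path, call. = FALSE)
  raw <- parse_config_file(path)
  rig_from_list(raw, context = path)
}

parse_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

rig_from_list <- function(raw, context = "rig config") {
  need <- function(block, field, where) {
    if (is.null(block[[field]])) {
      stop(sprintf("%s: missing field '%s' in %s", context, field, where),
           call. = FALSE)
    }
    block[[field]]
  }
  num3 <- function(x, field, where) {
    x <- as.numeric(unlist(x))
    if (length(x) != 3 || anyNA(x)) {
      stop(sprintf("%s: field '%s' in %s must be 3 numbers", context, field, where),
           call. = FALSE)
    }
    x
  }
  obs_block <- raw$observer
  if (is.null(obs_block)) obs_block <- list(position_m = c(0, 0, 0))
  opos <- num3(obs_block$position_m %||% c(0, 0, 0), "position_m", "observer")
  orot <- num3(obs_block$rotation_deg %||% c(0, 0, 0), "rotation_deg", "observer")
  observer <- observer_spec(
    pose = pose(opos, rotation_from_euler(orot[1], orot[2], orot[3])),
    interpupillary_distance = as.numeric(obs_block$interpupillary_distance_m %||% 0)
  )
  disp_raw <- raw$displays
  if (is.null(disp_raw) || length(disp_raw) == 0) {
    stop(context, ": missing field 'displays' (need at least one display block)",
         call. = FALSE)
  }
  displays <- lapply(seq_along(disp_raw), function(k) {
    d <- disp_raw[[k]]
    where <- sprintf("displays[%d]", k)
    nm <- as.character(need(d, "name", where))
    p <- num3(need(d, "position_m", where), "position_m", where)
    r <- num3(d$rotation_deg %||% c(0, 0, 0), "rotation_deg", where)
    res <- as.integer(unlist(need(d, "resolution", where)))
    if (length(res) != 2) {
      stop(sprintf("%s: 'resolution' in %s must be [x, y]", context, where),
           call. = FALSE)
    }
    display_spec(
      name = nm,
      pose = pose(p, rotation_from_euler(r[1], r[2], r[3])),
      width = as.numeric(need(d, "width_m", where)),
      height = as.numeric(need(d, "height_m", where)),
      resolution_x = res[1], resolution_y = res[2]
    )
  })
  names(displays) <- vapply(displays, `[[`, "", "name")
  structure(list(observer = observer, displays = displays), class = "rig_config")
}

#' Write a rig configuration file
#'
#' Inverse of [read_rig_config()]; the output is directly reloadable.
#' Used by the calibration pipeline to persist recovered display poses.
#'
#' @param rig A `rig_config` (or [calibration_result()] via its method).
#' @param path Output `.yml`/`.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_rig_config <- function(rig, path) {
  stopifnot(inherits(rig, "rig_config"))
  as_block <- function(d) {
    list(
      name = d$name,
      position_m = as.numeric(d$pose$position),
      rotation_deg = as.numeric(euler_from_rotation(d$pose$rotation)),
      width_m = d$width, height_m = d$height,
      resolution = c(d$resolution_x, d$resolution_y)
    )
  }
  out <- list(
    observer = list(
      position_m = as.numeric(rig$observer$pose$position),
      rotation_deg = as.numeric(euler_from_rotation(rig$observer$pose$rotation)),
      interpupillary_distance_m = rig$observer$interpupillary_distance
    ),
    displays = lapply(unname(rig$displays), as_block)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 12)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
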