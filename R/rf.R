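# Sparse-noise reverse correlation.  Spike trains are binned at 60 Hz,
# smoothed with a Gaussian filter, and the receptive field is mapped as
# the average response elicited by the appearance of a stimulus in each
# grid location, baseline-corrected by the grand mean of the signal.  A
# synthetic Poisson neuron exercises the whole pipeline for parameter
# recovery.

RF_RATE_HZ <- 60

#' Bin spike times and smooth the rate
#'
#' Counts spikes in 1/60 s bins, divides by the bin width, and convolves
#' with a unit-sum Gaussian kernel (standard deviation `smooth_sd_s`,
#' truncated at 3 sigma, reflected at the edges).  A 300 ms filter width
#' is taken as the kernel standard deviation by default; set
#' `smooth_fwhm_s` instead to interpret a width as FWHM.
#'
#' @param spikes Numeric vector of spike times, s, sorted ascending.
#' @param t_start,t_end Trace span, s, `t_end > t_start`.
#' @param smooth_sd_s Gaussian kernel SD, s (default 0.3). Zero disables
#'   smoothing.
#' @param smooth_fwhm_s Optional; if given, overrides `smooth_sd_s` with
#'   `fwhm / (2 sqrt(2 log 2))`.
#' @return A `rate_trace`: tibble `{t_s, rate_hz}` on the uniform 60 Hz
#'   grid (times at bin centres).
#' @export
bin_and_smooth_rate <- function(spikes, t_start, t_end,
                                smooth_sd_s = 0.3, smooth_fwhm_s = NULL) {
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (is.unsorted(spikes)) stop("spike times must be sorted ascending")
  if (length(spikes) && any(spikes < 0)) stop("spike times must be non-negative")
  if (!is.null(smooth_fwhm_s)) smooth_sd_s <- smooth_fwhm_s / (2 * sqrt(2 * log(2)))
  dt <- 1 / RF_RATE_HZ
  edges <- seq(t_start, t_end, by = dt)
  if (edges[length(edges)] < t_end - 1e-12) edges <- c(edges, edges[length(edges)] + dt)
  counts <- graphics::hist(spikes[spikes >= t_start & spikes < max(edges)],
                           breaks = edges, plot = FALSE)$counts
  rate <- counts / dt
  if (smooth_sd_s > 0) {
    half <- max(1L, ceiling(3 * smooth_sd_s / dt))
    kern <- stats::dnorm(seq(-half, half) * dt, sd = smooth_sd_s)
    kern <- kern / sum(kern)
    rate <- convolve_reflect(rate, kern)
  }
  centres <- edges[-length(edges)] + dt / 2
  structure(
    tibble::tibble(t_s = centres, rate_hz = rate),
    class = c("rate_trace", class(tibble::tibble()))
  )
}

# Convolution with reflected (mirrored) edge padding.
convolve_reflect <- function(x, kern) {
  half <- (length(kern) - 1L) %/% 2L
  n <- length(x)
  pad <- min(half, n)
  left <- if (pad > 0) x[pad:1] else numeric(0)        # symmetric padding
  right <- if (pad > 0) x[n:(n - pad + 1)] else numeric(0)
  xx <- c(left, x, right)
  if (pad < half) xx <- c(rep(xx[1], half - pad), xx, rep(xx[length(xx)], half - pad))
  out <- stats::filter(xx, kern, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Map a receptive field by reverse correlation
#'
#' For each sparse-noise grid location the signal is averaged over
#' `[onset, onset + window_s]` across that location's presentations; the
#' grand mean of the whole signal is subtracted as baseline.  Works
#' identically for spike-derived rates and continuous signals (LFP): the
#' map is agnostic to what the trace measures.
#'
#' @param signal A `rate_trace` (tibble `{t_s, rate_hz}`), or any tibble
#'   with those columns holding a uniformly sampled signal.
#' @param log Presentation log from [sparse_noise_log()] (columns
#'   `onset_s`, `row`, `col`, optionally `polarity`).
#' @param grid_rows,grid_cols Grid size of the stimulus.
#' @param window_s Response window after onset (default 0.2 s).
#' @param split_polarity If `TRUE`, return one map per polarity.
#' @return An `rf_map`: list with `$response` (rows x cols matrix of
#'   baseline-subtracted mean responses; `NA` for never-stimulated
#'   locations), `$n_presentations` (count matrix), `$baseline`, `$peak`
#'   (tibble with the peak location) and optionally `$by_polarity`.
#' @export
compute_rf <- function(signal, log, grid_rows, grid_cols,
                       window_s = 0.2, split_polarity = FALSE) {
  ts <- signal$t_s; y <- signal$rate_hz
  if (max(log$onset_s) + window_s > max(ts) + 1e-9) {
    stop("signal does not cover all presentations plus the response window")
  }
  baseline <- mean(y)
  dt <- stats::median(diff(ts))
  one_map <- function(lg) {
    resp <- matrix(NA_real_, grid_rows, grid_cols)
    npres <- matrix(0L, grid_rows, grid_cols)
    means <- numeric(nrow(lg))
    for (i in seq_len(nrow(lg))) {
      sel <- ts >= lg$onset_s[i] - dt / 2 & ts <= lg$onset_s[i] + window_s + dt / 2
      means[i] <- mean(y[sel])
    }
    agg <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(lg, .resp = means), .data$row, .data$col),
      m = mean(.data$.resp), n = dplyr::n(), .groups = "drop"
    )
    resp[cbind(agg$row, agg$col)] <- agg$m - baseline
    npres[cbind(agg$row, agg$col)] <- agg$n
    list(response = resp, n = npres)
  }
  full <- one_map(log)
  pk <- which(full$response == max(full$response, na.rm = TRUE), arr.ind = TRUE)[1, ]
  out <- list(
    response = full$response,
    n_presentations = full$n,
    baseline = baseline,
    window_s = window_s,
    peak = tibble::tibble(row = unname(pk[1]), col = unname(pk[2]),
                          response = max(full$response, na.rm = TRUE))
  )
  if (split_polarity && !is.null(log$polarity)) {
    out$by_polarity <- lapply(split(log, log$polarity),
                              function(lg) one_map(lg)$response)
  }
  structure(out, class = "rf_map")
}

#' @export
print.rf_map <- function(x, ...) {
  cat(sprintf(
    "<rf_map> %d x %d grid, peak %.3f at (%d, %d), baseline %.3f\n",
    nrow(x$response), ncol(x$response), x$peak$response,
    x$peak$row, x$peak$col, x$baseline
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rf_map <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$response)), times = ncol(x$response)),
    col = rep(seq_len(ncol(x$response)), each = nrow(x$response)),
    response = as.vector(x$response),
    n_presentations = as.vector(x$n_presentations)
  )
}

#' Write an RF map as a CSV matrix
#' @param map An `rf_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rf_map_csv <- function(map, path) {
  utils::write.table(map$response, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# --- Synthetic neuron ------------------------------------------------------

#' Synthetic sparse-noise neuron specification
#'
#' An inhomogeneous-Poisson model cell with a Gaussian receptive field on
#' the stimulus grid: during `[onset + latency, onset + latency +
#' response_duration]` of each presentation the rate is
#' `baseline + gain exp(-d^2 / 2 sigma^2)` where `d` is the grid distance
#' between the presented square and the RF centre; elsewhere it fires at
#' `baseline`.
#'
#' @param centre_row,centre_col RF centre, grid cells.
#' @param width_cells Gaussian sigma in grid cells (default 1).
#' @param gain_hz Peak rate increase, spikes/s, >= 0.
#' @param baseline_hz Baseline rate, spikes/s, >= 0.
#' @param latency_s Response latency, s (default 0.05).
#' @param response_duration_s Responsive window per presentation, s
#'   (default 0.1, matching the presentation duration).
#' @param polarity_preference `"both"`, `"black"` or `"white"`.
#' @param seed Integer seed.
#' @return A `synthetic_neuron_spec`.
#' @export
synthetic_neuron_spec <- function(centre_row, centre_col, width_cells = 1,
                                  gain_hz = 50, baseline_hz = 2,
                                  latency_s = 0.05,
                                  response_duration_s = 0.1,
                                  polarity_preference = "both",
                                  seed = 1L) {
  if (gain_hz < 0 || baseline_hz < 0) stop("gain and baseline must be >= 0")
  structure(
    list(centre_row = centre_row, centre_col = centre_col,
         width_cells = width_cells, gain_hz = gain_hz,
         baseline_hz = baseline_hz, latency_s = latency_s,
         response_duration_s = response_duration_s,
         polarity_preference = polarity_preference, seed = as.integer(seed)),
    class = "synthetic_neuron_spec"
  )
}

#' Simulate a synthetic neuron's response to a sparse-noise log
#'
#' Draws inhomogeneous-Poisson spikes: a homogeneous baseline over the
#' whole span plus, per presentation, an extra Poisson process at the
#' RF-dependent rate during the response window.  Reproducible from the
#' spec seed.
#'
#' @param spec A [synthetic_neuron_spec()].
#' @param log Presentation log from [sparse_noise_log()].
#' @return Sorted numeric vector of spike times (class `spike_train`).
#' @export
simulate_sparse_noise_neuron <- function(spec, log) {
  stopifnot(inherits(spec, "synthetic_neuron_spec"))
  dur <- if (nrow(log) > 1) stats::median(diff(log$onset_s)) else 0.1
  t_end <- max(log$onset_s) + dur + spec$latency_s + spec$response_duration_s
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  spikes <- if (spec$baseline_hz > 0) {
    n0 <- stats::rpois(1, spec$baseline_hz * t_end)
    stats::runif(n0, 0, t_end)
  } else numeric(0)
  responds <- if (spec$polarity_preference == "both" || is.null(log$polarity)) {
    rep(TRUE, nrow(log))
  } else log$polarity == spec$polarity_preference
  d2 <- (log$row - spec$centre_row)^2 + (log$col - spec$centre_col)^2
  extra <- spec$gain_hz * exp(-d2 / (2 * spec$width_cells^2)) * responds
  lam <- extra * spec$response_duration_s
  n_extra <- stats::rpois(nrow(log), lam)
  for (i in which(n_extra > 0)) {
    w0 <- log$onset_s[i] + spec$latency_s
    spikes <- c(spikes, stats::runif(n_extra[i], w0, w0 + spec$response_duration_s))
  }
  structure(sort(spikes), class = "spike_train")
}

#' Write / read spike times CSV (one column, seconds)
#' @param path CSV path.
#' @return Numeric spike times (for the reader).
#' @export
read_spike_csv <- function(path) {
  sort(readr::read_csv(path, show_col_types = FALSE)$spike_time_s)
}

#' @rdname read_spike_csv
#' @param spikes Numeric spike times.
#' @export
write_spike_csv <- function(spikes, path) {
  readr::write_csv(tibble::tibble(spike_time_s = as.numeric(spikes)), path)
  invisible(path)
}
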