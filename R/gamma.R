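# Display luminance linearisation.  Displays map command values v in
# [0, 1] to emitted luminance nonlinearly; measuring a handful of
# command/luminance pairs and fitting an offset-plus-power model
#   L(v) = L_min + (L_max - L_min) v^gamma
# lets commanded values be pre-distorted so luminance becomes linear in
# the requested value.

#' Fit a display gamma model
#'
#' Least-squares fit of `L(v) = L_min + (L_max - L_min) v^gamma` to
#' measured command/luminance pairs (Levenberg-Marquardt).
#'
#' @param measurements Data frame with columns `command` (in `[0, 1]`) and
#'   `luminance` (cd/m^2).  At least 4 distinct command values spanning
#'   `[0, 1]` are required and luminance must increase with command
#'   overall (rank correlation > 0.8; modest measurement noise is fine,
#'   decreasing curves are rejected).
#' @return A `gamma_model` with fields `L_min`, `L_max`, `gamma`,
#'   `sigma` (residual RMS, cd/m^2) and `n`.
#' @export
fit_gamma <- function(measurements) {
  v <- measurements$command
  L <- measurements$luminance
  if (is.null(v) || is.null(L)) stop("measurements need 'command' and 'luminance'")
  keep <- is.finite(v) & is.finite(L)
  v <- v[keep]; L <- L[keep]
  if (length(unique(v)) < 4) stop("need at least 4 distinct command values")
  if (min(v) > 0.05 || max(v) < 0.95) {
    stop("command values must span [0, 1] (include values near 0 and 1)")
  }
  if (any(v < 0 | v > 1)) stop("command values must lie in [0, 1]")
  if (stats::cor(v, L, method = "spearman") <= 0.8) {
    stop("luminance must increase with command (non-monotonic data)")
  }
  # starting values: range from the data, gamma from a log-log regression
  L0 <- min(L); L1 <- max(L)
  mid <- v > 0 & L > L0
  g0 <- if (sum(mid) >= 2) {
    stats::coef(stats::lm(log(pmax(L[mid] - L0, 1e-9) / (L1 - L0)) ~ log(v[mid])))[2]
  } else 2
  g0 <- min(10, max(0.2, g0))
  df <- data.frame(v = v, L = L)
  fit <- minpack.lm::nlsLM(
    L ~ Lmin + (Lmax - Lmin) * v^g,
    data = df,
    start = list(Lmin = L0, Lmax = L1, g = g0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)
  )
  cf <- stats::coef(fit)
  if (cf[["g"]] <= 0) stop("fitted gamma is not positive")
  if (cf[["Lmax"]] <= cf[["Lmin"]]) stop("fitted L_max must exceed L_min")
  structure(
    list(
      L_min = unname(cf[["Lmin"]]), L_max = unname(cf[["Lmax"]]),
      gamma = unname(cf[["g"]]),
      sigma = sqrt(mean(stats::resid(fit)^2)), n = length(v)
    ),
    class = "gamma_model"
  )
}

#' @export
print.gamma_model <- function(x, ...) {
  cat(sprintf(
    "<gamma_model> L = %.4g + (%.4g - %.4g) v^%.4f  (rms %.3g cd/m2, n = %d)\n",
    x$L_min, x$L_max, x$L_min, x$gamma, x$sigma, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gamma_model <- function(x, ...) {
  tibble::tibble(
    term = c("L_min", "L_max", "gamma"),
    estimate = c(x$L_min, x$L_max, x$gamma)
  )
}

#' @exportS3Method generics::glance
glance.gamma_model <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, L_min = x$L_min, L_max = x$L_max,
                 sigma = x$sigma, n = x$n)
}

#' Predict luminance from command values
#' @param object A `gamma_model`.
#' @param command Command values in `[0, 1]`.
#' @param ... Unused.
#' @return Luminance, cd/m^2.
#' @export
predict.gamma_model <- function(object, command, ...) {
  object$L_min + (object$L_max - object$L_min) * command^object$gamma
}

#' Inverse (linearising) lookup table of a gamma model
#'
#' For a requested linear value `x` the command is `x^(1/gamma)`, quantised
#' to `levels` steps, so that displayed luminance is linear in `x` to
#' within one quantisation step.
#'
#' @param model A `gamma_model`.
#' @param levels Number of quantisation levels (default 256).
#' @return Tibble `{value, command}` with `levels` rows.
#' @export
gamma_lut <- function(model, levels = 256) {
  x <- seq(0, 1, length.out = levels)
  cmd <- x^(1 / model$gamma)
  tibble::tibble(value = x, command = round(cmd * (levels - 1)) / (levels - 1))
}

#' Linearise an image through a gamma model
#'
#' Replaces each requested value `x` by the command `x^(1/gamma)` quantised
#' to `levels` steps; feeding the result through the display's forward
#' model yields luminance linear in `x`.
#'
#' @param image `rw_image` or matrix of requested linear values in `[0, 1]`.
#' @param model A `gamma_model`.
#' @param levels Quantisation levels (default 256).
#' @return Linearised `rw_image` of command values.
#' @export
linearize_image <- function(image, model, levels = 256) {
  m <- as.matrix(unclass(image))
  cmd <- pmin(1, pmax(0, as.numeric(m)))^(1 / model$gamma)
  rw_image(matrix(round(cmd * (levels - 1)) / (levels - 1), nrow = nrow(m)))
}

#' Read luminance measurements from CSV
#'
#' Expects columns `command` and `cd_per_m2` (renamed to `luminance`).
#' @param path CSV path.
#' @return Tibble with `command` and `luminance`.
#' @export
read_luminance_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(d$cd_per_m2) && is.null(d$luminance)) {
    d <- dplyr::rename(d, luminance = "cd_per_m2")
  }
  d
}

#' Write a linearising LUT to CSV
#' @param model A `gamma_model`.
#' @param path Output path.
#' @param levels Quantisation levels.
#' @return `path`, invisibly.
#' @export
write_gamma_lut <- function(model, path, levels = 256) {
  readr::write_csv(gamma_lut(model, levels), path)
  invisible(path)
}
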