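#' @useDynLib thermospec, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm approx qlogis
NULL

#' Exponential spectrum of a thermal step response
#'
#' A discrete spectrum of thermal time constants and amplitudes describing a
#' multi-exponential temperature rise
#' \deqn{T(t) = \sum_i T_i\,(1 - e^{-t/\tau_i}),}
#' the step response of a Foster R-C ladder with one \eqn{(\tau_i, T_i)} pair
#' per cell. The standard model order for skin thermography is four
#' components. Components are always stored sorted by increasing \eqn{\tau}:
#' the model is invariant under component permutation, so the sorted order is
#' the canonical representative (and the only well-defined regression
#' target).
#'
#' @param tau Positive time constants, in seconds (physical) or
#'   dimensionless on the normalized scale.
#' @param amp Non-negative amplitudes, one per time constant, in degrees C or
#'   dimensionless.
#' @param normalized Logical; `TRUE` when both `tau` and `amp` live on the
#'   normalized \eqn{[0, 1]} scale used for network training.
#' @return An object of class `exp_spectrum`: a list with elements `tau`,
#'   `amp` (both sorted by `tau` ascending) and `normalized`.
#' @examples
#' s <- exp_spectrum(tau = c(0.5, 0.1, 0.9, 0.3), amp = c(1, 2, 3, 4) / 10)
#' s$tau   # sorted ascending
#' @export
exp_spectrum <- function(tau, amp, normalized = FALSE) {
  if (length(tau) != length(amp) || length(tau) < 1L)
    stop("`tau` and `amp` must have equal, positive length")
  if (!all(is.finite(tau)) || !all(is.finite(amp)))
    stop("non-finite spectrum parameters")
  if (any(tau <= 0))
    stop("all time constants must be strictly positive")
  if (any(amp < 0))
    stop("amplitudes must be non-negative")
  if (normalized && (any(tau > 1) || any(amp > 1)))
    warning("normalized spectrum has parameters outside [0, 1]; ",
            "outside the trained range")
  o <- order(tau)
  structure(list(tau = as.numeric(tau[o]), amp = as.numeric(amp[o]),
                 normalized = isTRUE(normalized)),
            class = "exp_spectrum")
}

#' @export
print.exp_spectrum <- function(x, ...) {
  cat(sprintf("Exponential spectrum (%d components, %s units)\n",
              length(x$tau), if (x$normalized) "normalized" else "physical"))
  print(data.frame(component = seq_along(x$tau), tau = x$tau, amp = x$amp),
        row.names = FALSE)
  invisible(x)
}

#' Canonicalize component order
#'
#' Reorders the components of a spectrum by ascending time constant, moving
#' each amplitude together with its \eqn{\tau}. The forward model is
#' unchanged by reordering; sorting resolves the label-permutation symmetry.
#'
#' @param spectrum An [exp_spectrum()].
#' @return The same spectrum with components sorted by `tau` ascending.
#' @export
sort_components <- function(spectrum) {
  stopifnot(inherits(spectrum, "exp_spectrum"))
  o <- order(spectrum$tau)
  spectrum$tau <- spectrum$tau[o]
  spectrum$amp <- spectrum$amp[o]
  spectrum
}

#' Non-uniform time grid, dense at early times
#'
#' Builds the logarithmically spaced sampling grid used to represent
#' temperature-rise curves: \eqn{t_k = t_{end}\,(10^{d k/n} - 1)/(10^d - 1)}
#' for \eqn{k = 1, \dots, n}. Sample spacing grows monotonically with index,
#' so the fast initial transient -- which carries most of the information
#' about the small time constants -- is sampled densely while the
#' quasi-steady-state tail is sampled sparsely. With the default density
#' exponent `d = 3`, about two thirds of the samples fall in the first tenth
#' of the interval. The grid starts at a small positive time (the \eqn{t = 0}
#' sample of a rise curve is identically zero and carries no information) and
#' ends exactly at `t_end`.
#'
#' @param n Number of samples (>= 2); the network input length is 1024.
#' @param t_end End of the time interval (seconds, or 1 for the normalized
#'   axis).
#' @param density Positive density exponent `d`; larger values concentrate
#'   more samples at early times.
#' @return An object of class `time_grid`: list with `samples` (strictly
#'   increasing, length `n`), `t_end`, and `density`.
#' @examples
#' g <- time_grid(1024, t_end = 1)
#' mean(g$samples <= 0.1)  # over half the samples in the first 10%
#' @export
time_grid <- function(n = 1024L, t_end = 1.0, density = 3.0) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2")
  if (!is.finite(t_end) || t_end <= 0) stop("`t_end` must be positive")
  if (!is.finite(density) || density <= 0) stop("`density` must be positive")
  k <- seq_len(n)
  samples <- t_end * (10 ^ (density * k / n) - 1) / (10 ^ density - 1)
  samples[n] <- t_end  # exact endpoint
  structure(list(samples = samples, t_end = t_end, density = density),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "Time grid: %d samples on (0, %g], density %g (%.0f%% in first 10%%)\n",
    length(x$samples), x$t_end, x$density,
    100 * mean(x$samples <= 0.1 * x$t_end)))
  invisible(x)
}

#' Evaluate the multi-exponential forward model on a grid
#'
#' Computes the temperature rise \eqn{T(t_k) = \sum_i T_i (1 - e^{-t_k/\tau_i})}
#' at every sample of a time grid. The curve is 0 at \eqn{t = 0}, strictly
#' increasing for positive amplitudes, and approaches \eqn{\sum_i T_i}
#' (the sum of amplitudes) in the quasi-steady state.
#'
#' @param spectrum An [exp_spectrum()].
#' @param grid A [time_grid()] on the same time units as `spectrum`.
#' @return An object of class `temperature_curve`: list with `grid` and
#'   `values` (one reading per grid sample).
#' @examples
#' s <- exp_spectrum(rep(1, 4), rep(0.25, 4))
#' g <- time_grid(16, t_end = 1)
#' evaluate_curve(s, g)$values[16]  # 1 - exp(-1)
#' @export
evaluate_curve <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "exp_spectrum"), inherits(grid, "time_grid"))
  v <- drop((1 - exp(-outer(grid$samples, 1 / spectrum$tau))) %*% spectrum$amp)
  temperature_curve(grid, v)
}

#' Construct a sampled temperature curve
#'
#' @param grid A [time_grid()].
#' @param values Numeric readings, one per grid sample (degrees C or
#'   dimensionless).
#' @return An object of class `temperature_curve`.
#' @export
temperature_curve <- function(grid, values) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(values) != length(grid$samples))
    stop("`values` and grid must have equal length")
  if (!all(is.finite(values))) stop("non-finite curve values")
  structure(list(grid = grid, values = as.numeric(values)),
            class = "temperature_curve")
}

#' @export
print.temperature_curve <- function(x, ...) {
  cat(sprintf("Temperature curve: %d samples on (0, %g], range [%.4g, %.4g]\n",
              length(x$values), x$grid$t_end, min(x$values), max(x$values)))
  invisible(x)
}

#' Scaling between normalized and physical units
#'
#' The pair of multiplicative factors that maps the normalized
#' \eqn{[0, 1]} training scale to physical units: `t_scale` seconds per
#' normalized time unit (the duration of the measurement window) and
#' `temp_scale` degrees C per normalized temperature unit (the
#' temperature-rise span). Time constants scale with time, amplitudes with
#' temperature; normalize and rescale are exact inverses.
#'
#' @param t_scale Seconds per normalized time unit (> 0).
#' @param temp_scale Degrees C per normalized temperature unit (> 0).
#' @return An object of class `scaling_transform`.
#' @export
scaling_transform <- function(t_scale, temp_scale) {
  if (!is.finite(t_scale) || t_scale <= 0 ||
      !is.finite(temp_scale) || temp_scale <= 0)
    stop("scale factors must be strictly positive")
  structure(list(t_scale = as.numeric(t_scale),
                 temp_scale = as.numeric(temp_scale)),
            class = "scaling_transform")
}

#' Normalize a physical spectrum to the [0, 1] training scale
#'
#' Divides time constants by `t_scale` and amplitudes by `temp_scale`. If a
#' resulting parameter falls outside \eqn{[0, 1]} a warning (not an error) is
#' raised: measured data preprocessed with its own duration and span always
#' lands inside the range, so an out-of-range value signals a preprocessing
#' fault.
#'
#' @param spectrum A physical-unit [exp_spectrum()].
#' @param transform A [scaling_transform()].
#' @return A normalized `exp_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, transform) {
  stopifnot(inherits(spectrum, "exp_spectrum"),
            inherits(transform, "scaling_transform"))
  exp_spectrum(spectrum$tau / transform$t_scale,
               spectrum$amp / transform$temp_scale,
               normalized = TRUE)
}

#' Rescale a normalized spectrum to physical units
#'
#' Multiplies time constants by `t_scale` (seconds) and amplitudes by
#' `temp_scale` (degrees C); the exact inverse of [normalize_spectrum()].
#'
#' @param spectrum A normalized [exp_spectrum()].
#' @param transform A [scaling_transform()].
#' @return A physical-unit `exp_spectrum`.
#' @export
rescale_spectrum <- function(spectrum, transform) {
  stopifnot(inherits(spectrum, "exp_spectrum"),
            inherits(transform, "scaling_transform"))
  exp_spectrum(spectrum$tau * transform$t_scale,
               spectrum$amp * transform$temp_scale,
               normalized = FALSE)
}

#' Write / read a spectrum as JSON
#'
#' Serializes the spectrum as `{tau, amp, units: {time, temp}}`, with units
#' `"s"`/`"C"` for physical values and `"norm"` for normalized ones.
#'
#' @param spectrum An [exp_spectrum()].
#' @param path File path.
#' @return `write_spectrum_json()` returns `path` invisibly;
#'   `read_spectrum_json()` returns an `exp_spectrum`.
#' @export
write_spectrum_json <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "exp_spectrum"))
  units <- if (spectrum$normalized) list(time = "norm", temp = "norm")
           else list(time = "s", temp = "C")
  jsonlite::write_json(list(tau = spectrum$tau, amp = spectrum$amp,
                            units = units),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
read_spectrum_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  exp_spectrum(x$tau, x$amp, normalized = identical(x$units$time, "norm"))
}

#' Write a temperature curve as two-column CSV
#'
#' Column 1 is time, column 2 the temperature reading; one header line.
#' Files in this layout are read back with [read_measurement()].
#'
#' @param curve A [temperature_curve()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "temperature_curve"))
  utils::write.csv(data.frame(time = curve$grid$samples,
                              temperature = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}
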