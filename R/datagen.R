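# Synthetic corpus generation. All randomness goes through a local
# Mersenne-Twister stream so generation is a pure function of (n, grid,
# seed, variance) and never disturbs the caller's RNG state.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Draw one random spectrum from the training prior
#'
#' Time constants are drawn uniformly on `[tau_min, 1]` and amplitudes
#' uniformly on `[0, 1]`, the normalized ranges the network is trained on;
#' the result is canonically sorted by tau. The small positive lower bound
#' `tau_min` excludes degenerate components whose transient has already
#' decayed before the first grid sample and which are therefore
#' indistinguishable from a constant offset.
#'
#' Uses the current RNG state; seed the session (or use [build_dataset()],
#' which manages its own stream) for reproducibility.
#'
#' @param n_components Number of exponential components (default 4).
#' @param tau_min Lower bound of the time-constant range (default 0.001).
#' @return A normalized [exp_spectrum()].
#' @export
sample_spectrum <- function(n_components = 4L, tau_min = 0.001) {
  exp_spectrum(runif(n_components, tau_min, 1),
               runif(n_components, 0, 1), normalized = TRUE)
}

#' Generate a matched curve/parameter dataset
#'
#' Draws `n` random spectra from the training prior and evaluates the
#' forward model for each on a shared time grid, producing the matrices the
#' network consumes: curves (`n` x 1024) and targets (`n` x 8, the four
#' tau sorted ascending followed by their four co-sorted amplitudes, all in
#' \eqn{[0, 1]}). Generation is deterministic given `(n, grid, seed)`.
#'
#' @param n Number of curves (the reference protocol uses 10,000 for
#'   training and 1000 for validation).
#' @param grid Shared [time_grid()] (default the 1024-point normalized grid).
#' @param seed Integer seed for the generator's private RNG stream.
#' @param tau_min Lower bound of the time-constant range.
#' @return An object of class `curve_dataset`: list with `curves`,
#'   `targets`, `grid`, and `meta` (`n`, `seed`, `variance = 0`,
#'   `tau_min`).
#' @examples
#' d <- build_dataset(5, time_grid(64), seed = 1)
#' dim(d$curves); dim(d$targets)
#' @export
build_dataset <- function(n, grid = time_grid(), seed = 1L, tau_min = 0.001) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  stopifnot(inherits(grid, "time_grid"))
  local_seed(seed, {
    # row-wise draws in the same order as repeated sample_spectrum() calls
    par <- matrix(runif(n * 8L), nrow = n, ncol = 8L, byrow = TRUE)
    tau <- tau_min + (1 - tau_min) * par[, 1:4, drop = FALSE]
    amp <- par[, 5:8, drop = FALSE]
    ord <- t(apply(tau, 1L, order))
    idx <- cbind(rep(seq_len(n), 4L), as.vector(ord))
    tau_s <- matrix(tau[idx], nrow = n)
    amp_s <- matrix(amp[idx], nrow = n)
    curves <- matrix(0, nrow = n, ncol = length(grid$samples))
    for (j in 1:4) {
      curves <- curves +
        amp_s[, j] * (1 - exp(-outer(1 / tau_s[, j], grid$samples)))
    }
    structure(list(curves = curves,
                   targets = cbind(tau_s, amp_s),
                   grid = grid,
                   meta = list(n = n, seed = as.integer(seed), variance = 0,
                               tau_min = tau_min)),
              class = "curve_dataset")
  })
}

#' @export
print.curve_dataset <- function(x, ...) {
  cat(sprintf(
    "Curve dataset: %d curves x %d samples (seed %d, noise variance %g)\n",
    x$meta$n, ncol(x$curves), x$meta$seed, x$meta$variance))
  invisible(x)
}

#' Extract one curve of a dataset
#'
#' @param dataset A `curve_dataset`.
#' @param i Row index.
#' @return A [temperature_curve()] on the dataset's grid.
#' @export
dataset_curve <- function(dataset, i) {
  stopifnot(inherits(dataset, "curve_dataset"))
  temperature_curve(dataset$grid, dataset$curves[i, ])
}

#' Extract one target spectrum of a dataset
#'
#' @param dataset A `curve_dataset`.
#' @param i Row index.
#' @return A normalized [exp_spectrum()].
#' @export
dataset_spectrum <- function(dataset, i) {
  stopifnot(inherits(dataset, "curve_dataset"))
  exp_spectrum(dataset$targets[i, 1:4], dataset$targets[i, 5:8],
               normalized = TRUE)
}

#' Corrupt dataset curves with additive Gaussian noise
#'
#' Adds an independent zero-mean Gaussian draw of the given variance to
#' every curve sample, emulating the residual measurement noise of
#' ROI-averaged thermography signals after motion correction. Targets are
#' untouched: the noise protocol perturbs the network input only. The
#' reference noise levels are variances 0.0001 to 0.005 on the normalized
#' temperature scale.
#'
#' @param dataset A `curve_dataset`.
#' @param variance Noise variance (>= 0) on the dataset's temperature scale.
#' @param seed Integer seed for the noise stream (independent of the
#'   generation seed).
#' @return A `curve_dataset` with noisy `curves`, identical `targets`, and
#'   `meta$variance`/`meta$noise_seed` updated.
#' @export
add_noise <- function(dataset, variance, seed = 1L) {
  stopifnot(inherits(dataset, "curve_dataset"))
  if (!is.finite(variance) || variance < 0)
    stop("`variance` must be non-negative")
  if (variance == 0) return(dataset)
  local_seed(seed, {
    noise <- matrix(rnorm(length(dataset$curves), 0, sqrt(variance)),
                    nrow = nrow(dataset$curves))
    dataset$curves <- dataset$curves + noise
    dataset$meta$variance <- variance
    dataset$meta$noise_seed <- as.integer(seed)
    dataset
  })
}

#' Save / load a dataset container
#'
#' One self-contained file per split (curves, targets, grid, meta), plus an
#' optional JSON sidecar with the generation metadata.
#'
#' @param dataset A `curve_dataset`.
#' @param path File path (`.rds`).
#' @param sidecar Write `<path>.json` with `meta`? Default `TRUE`.
#' @return `save_dataset()` returns `path` invisibly; `load_dataset()`
#'   returns the `curve_dataset`.
#' @export
save_dataset <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "curve_dataset"))
  saveRDS(dataset, path)
  if (sidecar)
    jsonlite::write_json(dataset$meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "curve_dataset"))
  x
}
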