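# Error metrics mirroring the reference tables: per-component MSE of the
# time constants and amplitudes, plus the MSE of the reconstructed
# temperature curve, reported per noise variance.

#' Per-component mean squared errors
#'
#' Computes the MSE between predicted and true parameter matrices per
#' component index (1..4), separately for the time-constant and amplitude
#' blocks. Both matrices must be canonically tau-sorted per row, the layout
#' [predict_matrix()] and `curve_dataset` targets share; pairing is by
#' component index, not by optimal assignment.
#'
#' @param predicted,truth Numeric `n x 8` matrices.
#' @return List with `tau` and `amp` (length-4 MSE vectors) and their means
#'   `tau_mean`, `amp_mean`.
#' @export
component_mse <- function(predicted, truth) {
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1)
  if (!all(dim(predicted) == dim(truth)))
    stop("`predicted` and `truth` must have equal dimensions")
  k <- ncol(predicted) %/% 2L
  d2 <- (predicted - truth)^2
  tau <- colMeans(d2[, seq_len(k), drop = FALSE])
  amp <- colMeans(d2[, k + seq_len(k), drop = FALSE])
  list(tau = unname(tau), amp = unname(amp),
       tau_mean = mean(tau), amp_mean = mean(amp))
}

#' Curve-reconstruction mean squared error
#'
#' Regenerates each curve from its predicted parameters through the forward
#' model and returns the MSE against the input curves, averaged over all
#' grid samples and all curves. Computed on the normalized 1024-point
#' non-uniform grid, the network's own input domain.
#'
#' @param predicted Numeric `n x 8` matrix of predicted parameters.
#' @param curves Numeric `n x m` matrix of input curves.
#' @param grid The [time_grid()] the curves are sampled on (`m` samples).
#' @return Scalar MSE.
#' @export
curve_mse <- function(predicted, curves, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1)
  if (ncol(curves) != length(grid$samples))
    stop("curve length does not match the grid")
  if (nrow(predicted) != nrow(curves)) stop("batch size mismatch")
  k <- ncol(predicted) %/% 2L
  recon <- matrix(0, nrow(curves), ncol(curves))
  for (j in seq_len(k)) {
    recon <- recon +
      predicted[, k + j] * (1 - exp(-outer(1 / predicted[, j], grid$samples)))
  }
  mean((recon - curves)^2)
}

#' Evaluate a model on one dataset
#'
#' Predicts every curve of the dataset and assembles the standard error
#' report: per-component and mean MSE of tau and amplitudes plus the
#' curve-reconstruction MSE.
#'
#' @param model A trained `cnn_model`.
#' @param dataset A `curve_dataset` (clean or noisy).
#' @return An object of class `evaluation_report`: list with `tau_mse`,
#'   `amp_mse` (length 4), `tau_mean`, `amp_mean`, `curve_mse`, `variance`,
#'   `n_test`.
#' @export
evaluate_model <- function(model, dataset) {
  stopifnot(inherits(model, "cnn_model"), inherits(dataset, "curve_dataset"))
  pred <- predict_matrix(model, dataset$curves)
  cm <- component_mse(pred, dataset$targets)
  structure(list(tau_mse = cm$tau, amp_mse = cm$amp,
                 tau_mean = cm$tau_mean, amp_mean = cm$amp_mean,
                 curve_mse = curve_mse(pred, dataset$curves, dataset$grid),
                 variance = dataset$meta$variance,
                 n_test = dataset$meta$n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(render_report(list(x)))
  invisible(x)
}

#' Noise-robustness sweep
#'
#' Evaluates a trained model on the same clean test curves corrupted at a
#' series of Gaussian noise variances (one independently seeded injection
#' per variance, derived deterministically from `seed` and the variance
#' index). Variance 0 reproduces the clean-data protocol bit for bit.
#'
#' @param model A trained `cnn_model`.
#' @param clean_test A clean `curve_dataset`.
#' @param variances Noise variances; default the reference levels
#'   `c(1, 5, 10, 15, 25, 50) * 1e-4`.
#' @param seed Base seed for the noise injections.
#' @return List of `evaluation_report`, one per variance.
#' @export
noise_sweep <- function(model, clean_test,
                        variances = c(1e-4, 5e-4, 1e-3, 1.5e-3, 2.5e-3, 5e-3),
                        seed = 1L) {
  stopifnot(inherits(model, "cnn_model"), inherits(clean_test, "curve_dataset"))
  lapply(seq_along(variances), function(i) {
    noisy <- add_noise(clean_test, variances[i], seed = as.integer(seed) + i)
    evaluate_model(model, noisy)
  })
}

#' Render evaluation reports as a table
#'
#' Formats one or more reports in the reference layout: rows for components
#' 1-4 plus a mean row, columns for the tau MSE, amplitude MSE, and (on the
#' first row of each group) the curve MSE, grouped by noise variance.
#'
#' @param reports A single `evaluation_report` or a list of them (e.g., from
#'   [noise_sweep()]).
#' @param file Optional path; when given the table is also written there as
#'   CSV.
#' @return The formatted table as a character string (invisibly the
#'   underlying data.frame is attached as attribute `"data"`).
#' @export
render_report <- function(reports, file = NULL) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "evaluation_report")))
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(variance = r$variance,
               component = c("1", "2", "3", "4", "mean"),
               tau_mse = c(r$tau_mse, r$tau_mean),
               amp_mse = c(r$amp_mse, r$amp_mean),
               curve_mse = c(r$curve_mse, NA, NA, NA, NA))
  }))
  if (!is.null(file)) utils::write.csv(rows, file, row.names = FALSE)
  lines <- c(sprintf("%-10s %-9s %-10s %-10s %-10s",
                     "variance", "component", "tau_mse", "amp_mse",
                     "curve_mse"))
  for (i in seq_len(nrow(rows))) {
    lines <- c(lines, sprintf(
      "%-10s %-9s %-10.5f %-10.5f %-10s",
      ifelse(rows$component[i] == "1", format(rows$variance[i]), ""),
      rows$component[i], rows$tau_mse[i], rows$amp_mse[i],
      ifelse(is.na(rows$curve_mse[i]), "",
             sprintf("%.5f", rows$curve_mse[i]))))
  }
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  attr(out, "data") <- rows
  out
}

#' Read back a rendered report CSV
#'
#' @param file Path written by [render_report()].
#' @return The report data.frame.
#' @export
read_report_csv <- function(file) {
  utils::read.csv(file, colClasses = c(component = "character"))
}
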