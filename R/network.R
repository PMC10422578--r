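#' Configuration of the regression CNN
#'
#' Collects architecture and optimization settings for the 9-layer network
#' that maps a 1024-sample normalized temperature curve to the 8 regression
#' targets (4 sorted time constants, 4 co-sorted amplitudes). The reference
#' protocol: stochastic gradient descent, sigmoid activations, weighted loss
#' `0.2 * mse(tau) + 0.8 * mse(amp)`, 5000 epochs over 10,000 training and
#' 1000 validation curves. The loss down-weights the time constants because
#' they dominate the curve shape and are otherwise learned at the expense of
#' the amplitudes.
#'
#' Optimizer settings beyond "SGD" are free choices: defaults are learning
#' rate 0.05 with momentum 0.9 and batch size 64, conventional stable
#' settings for sigmoid networks (see the package vignette for how they
#' were picked).
#'
#' @param epochs Hard cap on training epochs (default 5000, the reference
#'   protocol; scale down for desk-scale runs).
#' @param batch_size Minibatch size.
#' @param learning_rate SGD learning rate at epoch 1.
#' @param lr_decay Multiplicative per-epoch learning-rate decay (1 = constant
#'   rate). The effective rate at epoch `e` is
#'   `learning_rate * lr_decay^(e-1)`.
#' @param momentum SGD momentum coefficient.
#' @param w_tau,w_amp Loss weights for the time-constant and amplitude
#'   blocks; must sum to 1.
#' @param n_input Curve length; must be a perfect square (reshaped to a
#'   square map for the 2-D convolutions). Fixed at 1024 for the reference
#'   architecture.
#' @param n_components Number of exponential components (output length is
#'   `2 * n_components`).
#' @param conv_filters Filters per hidden convolution layer.
#' @param n_conv Number of 32-filter convolution layers before the final
#'   single-filter one.
#' @param init Weight initialization scheme: `"lsuv"` (default;
#'   Glorot-uniform followed by layer-sequential variance calibration on a
#'   seeded batch of synthetic curves, so every sigmoid starts in its
#'   responsive range) or `"glorot"` (plain Glorot-uniform).
#' @param seed Integer seed for weight initialization and minibatch
#'   shuffling.
#' @return An object of class `network_config`.
#' @export
network_config <- function(epochs = 5000L, batch_size = 64L,
                           learning_rate = 0.05, lr_decay = 1.0,
                           momentum = 0.9,
                           w_tau = 0.2, w_amp = 0.8,
                           n_input = 1024L, n_components = 4L,
                           conv_filters = 32L, n_conv = 6L,
                           init = c("lsuv", "glorot"), seed = 1L) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("`epochs` must be >= 1")
  if (abs(w_tau + w_amp - 1) > 1e-12) stop("`w_tau + w_amp` must equal 1")
  if (w_tau < 0 || w_amp < 0) stop("loss weights must be non-negative")
  side <- sqrt(n_input)
  if (side != round(side))
    stop("`n_input` must be a perfect square (reshaped to a square map)")
  if (n_input != 1024L)
    stop("the reference architecture is fixed at n_input = 1024")
  if (batch_size < 1L || learning_rate <= 0 || momentum < 0 || momentum >= 1 ||
      lr_decay <= 0 || lr_decay > 1)
    stop("invalid optimizer settings")
  if (n_components < 1L) stop("`n_components` must be >= 1")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 momentum = momentum,
                 w_tau = w_tau, w_amp = w_amp,
                 n_input = as.integer(n_input),
                 n_output = 2L * as.integer(n_components),
                 n_components = as.integer(n_components),
                 conv_filters = as.integer(conv_filters),
                 n_conv = as.integer(n_conv),
                 kernel = 3L, activation = "sigmoid",
                 init = match.arg(init),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0(
    "CNN config: dense(%d) -> %d x conv(%d, 3x3, sigmoid) -> conv(1, 3x3)",
    " -> dense(%d, sigmoid)\n",
    "  loss %.1f*mse(tau) + %.1f*mse(amp); SGD lr %g, momentum %g,",
    " batch %d, epochs %d, seed %d\n"),
    x$n_input, x$n_conv, x$conv_filters, x$n_output,
    x$w_tau, x$w_amp, x$learning_rate, x$momentum,
    x$batch_size, x$epochs, x$seed))
  invisible(x)
}

# Glorot-uniform with the standard sigmoid gain correction: sigmoid(z) has
# slope 1/4 at the origin, so sigmoid-activated layers use gain 4 to keep
# activation and gradient variance from collapsing through the deep stack.
glorot <- function(nr, nc, fan_in, fan_out, gain = 1) {
  lim <- gain * sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained network
#'
#' Constructs the 9-layer architecture -- dense(1024, sigmoid), reshape to a
#' 32 x 32 x 1 map, six 2-D convolution layers (32 filters, 3 x 3, sigmoid,
#' same padding), one 2-D convolution layer (1 filter, 3 x 3, same padding,
#' linear), flatten back to 1024, dense(8, sigmoid) -- with Glorot-uniform
#' weights drawn from the config seed. The sigmoid output confines every
#' predicted parameter to (0, 1): the network cannot produce a negative time
#' constant, in contrast to unconstrained curve-fit optimizers. Output
#' biases start at the logit of the prior target means (the expected order
#' statistics of the sorted uniform time constants, and 1/2 for the
#' amplitudes), so the untrained network already predicts the prior mean.
#'
#' @param config A [network_config()].
#' @return An object of class `cnn_model`: list with `weights`, `config`,
#'   `trained`, `history`.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  nf <- config$conv_filters
  local_seed(config$seed, {
    W1 <- glorot(config$n_input, config$n_input,
                 config$n_input, config$n_input, gain = 4)
    conv_W <- list(); conv_b <- list()
    chans <- c(1L, rep(nf, config$n_conv - 1L))       # inputs of 32-filter convs
    for (l in seq_len(config$n_conv)) {
      cin <- chans[l]
      conv_W[[l]] <- glorot(nf, 9L * cin, 9L * cin, 9L * nf, gain = 4)
      conv_b[[l]] <- rep(0, nf)
    }
    conv_W[[config$n_conv + 1L]] <- glorot(1L, 9L * nf, 9L * nf, 9L)
    conv_b[[config$n_conv + 1L]] <- 0
    Wout <- glorot(config$n_input, config$n_output,
                   config$n_input, config$n_output)
    # prior means of the sorted-uniform taus are the order statistics
    # i/(k+1); amplitudes are plain uniforms with mean 1/2
    k <- config$n_components
    prior <- c(seq_len(k) / (k + 1), rep(0.5, k))
    weights <- list(W1 = W1, b1 = rep(0, config$n_input),
                    conv_W = conv_W, conv_b = conv_b,
                    Wout = Wout, bout = qlogis(prior))
    if (config$init == "lsuv") {
      calib <- build_dataset(128, time_grid(config$n_input),
                             seed = config$seed + 10000L)
      weights <- cnn_calibrate_cpp(weights, calib$curves,
                                   hidden_sd = 1.0, out_sd = 0.5)
    }
    structure(list(weights = weights, config = config,
                   trained = FALSE, history = NULL),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("cnn_model (%s)\n", if (x$trained) "trained" else "untrained"))
  print(x$config)
  if (!is.null(x$history))
    cat(sprintf("  %d epochs run; best val loss %.6g (epoch %d)\n",
                nrow(x$history), min(x$history$val_loss),
                which.min(x$history$val_loss)))
  invisible(x)
}

#' Weighted regression loss
#'
#' The training criterion: `w_tau * MSE(tau block) + w_amp * MSE(amplitude
#' block)`, with MSE taken over all batch rows and the 4 components of each
#' block. Inputs are `n x 8` matrices laid out as the regression targets
#' (columns 1-4 the sorted time constants, 5-8 the amplitudes).
#'
#' @param predicted,truth Numeric `n x 8` matrices (a single 8-vector is
#'   accepted).
#' @param w_tau,w_amp Block weights (default 0.2 / 0.8).
#' @return Scalar loss.
#' @examples
#' y <- matrix(runif(16), 2, 8)
#' weighted_loss(y, y)  # 0
#' @export
weighted_loss <- function(predicted, truth, w_tau = 0.2, w_amp = 0.8) {
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1)
  if (!all(dim(predicted) == dim(truth)) || ncol(predicted) %% 2L != 0L)
    stop("`predicted` and `truth` must be equal-shape n x 2k matrices")
  k <- ncol(predicted) %/% 2L
  d2 <- (predicted - truth)^2
  w_tau * mean(d2[, seq_len(k), drop = FALSE]) +
    w_amp * mean(d2[, k + seq_len(k), drop = FALSE])
}

#' Train the network on synthetic curve datasets
#'
#' Runs minibatch SGD with momentum under the weighted loss, tracking the
#' training and validation loss per epoch. The weights with the best
#' validation loss seen are retained (the epoch count stays a hard cap).
#' Training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model An untrained (or previously trained) `cnn_model`.
#' @param train_set,val_set `curve_dataset`s on the training grid with
#'   normalized, tau-sorted targets; generate them with different seeds so
#'   the splits are disjoint.
#' @param epochs Optional override of `config$epochs` for this call.
#' @param keep_best Retain the best-validation-loss checkpoint (default
#'   `TRUE`); with `FALSE` the final-epoch weights are kept.
#' @param verbose Print progress every `verbose` epochs (0 = silent).
#' @return The trained `cnn_model`, with `history` a data.frame of
#'   `epoch`, `train_loss`, `val_loss`.
#' @export
train_network <- function(model, train_set, val_set, epochs = NULL,
                          keep_best = TRUE, verbose = 0L) {
  stopifnot(inherits(model, "cnn_model"),
            inherits(train_set, "curve_dataset"),
            inherits(val_set, "curve_dataset"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (ncol(train_set$curves) != cfg$n_input)
    stop("training curves must have length ", cfg$n_input)
  if (ncol(train_set$targets) != cfg$n_output)
    stop("training targets must have ", cfg$n_output, " columns")
  fit <- cnn_train_cpp(model$weights,
                       train_set$curves, train_set$targets,
                       val_set$curves, val_set$targets,
                       as.integer(epochs), cfg$batch_size,
                       cfg$learning_rate, cfg$lr_decay, cfg$momentum,
                       cfg$w_tau, cfg$w_amp, cfg$seed,
                       isTRUE(keep_best), as.integer(verbose))
  model$weights <- fit$weights
  model$trained <- TRUE
  hist <- data.frame(epoch = seq_along(fit$train_loss),
                     train_loss = fit$train_loss,
                     val_loss = fit$val_loss)
  model$history <- if (is.null(model$history)) hist else
    rbind(model$history,
          transform(hist, epoch = epoch + max(model$history$epoch)))
  model
}

#' Predict parameter matrices for a batch of curves
#'
#' Applies the trained network to an `n x 1024` matrix of normalized curves
#' and returns the `n x 8` prediction matrix with each row re-sorted into
#' the canonical tau-ascending order (amplitudes moved with their tau).
#'
#' @param model A trained `cnn_model`.
#' @param curves Numeric `n x 1024` matrix.
#' @return Numeric `n x 8` matrix, rows canonically sorted.
#' @export
predict_matrix <- function(model, curves) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1)
  if (ncol(curves) != model$config$n_input)
    stop("curves must have length ", model$config$n_input)
  pred <- cnn_predict_cpp(model$weights, curves)
  k <- model$config$n_components
  out <- pred
  for (i in seq_len(nrow(pred))) {
    o <- order(pred[i, seq_len(k)])
    out[i, seq_len(k)] <- pred[i, o]
    out[i, k + seq_len(k)] <- pred[i, k + o]
  }
  out
}

#' Predict the spectrum of one temperature curve
#'
#' @param model A trained `cnn_model`.
#' @param curve A [temperature_curve()] sampled on the training grid with
#'   normalized values, or a numeric vector of length 1024.
#' @return A normalized [exp_spectrum()] (canonically sorted; all
#'   parameters in (0, 1) by construction of the sigmoid output).
#' @export
predict_spectrum <- function(model, curve) {
  v <- if (inherits(curve, "temperature_curve")) curve$values else curve
  p <- predict_matrix(model, v)
  k <- model$config$n_components
  exp_spectrum(p[1, seq_len(k)], p[1, k + seq_len(k)], normalized = TRUE)
}

#' Save / load a trained model
#'
#' The weight state and config are stored in one container file plus a JSON
#' sidecar with the config for inspection.
#'
#' @param model A `cnn_model`.
#' @param path File path (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   `cnn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "cnn_model"))
  x
}
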