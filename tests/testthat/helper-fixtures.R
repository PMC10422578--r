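# Shared fixtures. Everything is generated in code; the tiny trained model
# is cached so several test files can reuse one short training run.

table4_healthy <- list(
  tau = c(1.9486818, 18.936752, 113.21907, 230.25365),
  amp = c(1.354312, 1.1490566, 0.9453574, 0.8074841))

well_separated_spectrum <- function(tau = c(0.01, 0.05, 0.2, 0.8),
                                    amp = c(0.4, 0.3, 0.5, 0.6)) {
  exp_spectrum(tau, amp, normalized = TRUE)
}

# assemble a curve_dataset from explicit targets (tau sorted, amps co-sorted)
dataset_from_targets <- function(targets, grid = time_grid()) {
  targets <- as.matrix(targets)
  k <- ncol(targets) %/% 2L
  curves <- t(apply(targets, 1L, function(p) {
    evaluate_curve(exp_spectrum(p[seq_len(k)], p[k + seq_len(k)],
                                normalized = TRUE), grid)$values
  }))
  structure(list(curves = curves, targets = targets, grid = grid,
                 meta = list(n = nrow(targets), seed = NA_integer_,
                             variance = 0, tau_min = NA_real_)),
            class = "curve_dataset")
}

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- build_dataset(150, time_grid(), seed = 101)
      va <- build_dataset(50, time_grid(), seed = 102)
      m <- build_network(network_config(seed = 7))
      cache <<- train_network(m, tr, va, epochs = 4)
    }
    cache
  }
})

# physical-scale synthetic recording resembling the measurement protocol:
# 50 Hz sampling over `duration` seconds, baseline temperature added
write_synthetic_measurement <- function(path, tau, amp, duration = 360,
                                        baseline = 30, hz = 50) {
  t <- seq(0, duration, by = 1 / hz)
  y <- baseline + drop((1 - exp(-outer(t, 1 / tau))) %*% amp)
  utils::write.csv(data.frame(time = t, temperature = y), path,
                   row.names = FALSE)
  invisible(path)
}
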