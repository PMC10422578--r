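test_that("config invariants are enforced at construction", {
  expect_error(network_config(w_tau = 0.3, w_amp = 0.8), "equal 1")
  expect_error(network_config(epochs = 0), ">= 1")
  expect_error(network_config(n_input = 1000), "perfect square")
  expect_error(network_config(learning_rate = 0), "optimizer")
  cfg <- network_config()
  expect_identical(cfg$n_output, 8L)
  expect_identical(cfg$epochs, 5000L)       # reference protocol cap
  expect_identical(cfg$w_tau + cfg$w_amp, 1)
})

test_that("weighted loss matches its closed forms and an independent MSE", {
  y <- matrix(runif(40), 5, 8)
  expect_identical(weighted_loss(y, y), 0)

  # tau block off by a uniform 0.1 -> 0.2 * 0.01; amp block -> 0.8 * 0.01
  p_tau <- y; p_tau[, 1:4] <- y[, 1:4] + 0.1
  expect_equal(weighted_loss(p_tau, y), 0.002, tolerance = 1e-15)
  p_amp <- y; p_amp[, 5:8] <- y[, 5:8] + 0.1
  expect_equal(weighted_loss(p_amp, y), 0.008, tolerance = 1e-15)

  # independently coded (loop-based) reference on random batches
  set.seed(99)
  for (rep in 1:10) {
    pred <- matrix(runif(80), 10, 8); truth <- matrix(runif(80), 10, 8)
    mse_tau <- 0; mse_amp <- 0
    for (i in 1:10) for (j in 1:4) {
      mse_tau <- mse_tau + (pred[i, j] - truth[i, j])^2 / 40
      mse_amp <- mse_amp + (pred[i, j + 4] - truth[i, j + 4])^2 / 40
    }
    expect_equal(weighted_loss(pred, truth), 0.2 * mse_tau + 0.8 * mse_amp,
                 tolerance = 1e-14)
  }
  expect_error(weighted_loss(matrix(0, 2, 8), matrix(0, 3, 8)), "shape")
})

test_that("network construction is seeded and outputs live in (0, 1)", {
  m1 <- build_network(network_config(seed = 5))
  m2 <- build_network(network_config(seed = 5))
  x <- build_dataset(3, time_grid(), seed = 1)$curves
  p1 <- predict_matrix(m1, x); p2 <- predict_matrix(m2, x)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(dim(p1), c(3L, 8L))

  m3 <- build_network(network_config(seed = 6))
  expect_false(identical(predict_matrix(m3, x), p1))

  # untrained output bias encodes the prior mean of the sorted targets
  s0 <- predict_spectrum(m1, x[1, ])
  expect_true(s0$normalized)
  expect_identical(s0$tau, sort(s0$tau))
})

test_that("short training runs decrease the loss and are reproducible", {
  g <- time_grid()
  tr <- build_dataset(100, g, seed = 201)
  va <- build_dataset(40, g, seed = 202)
  # gentle learning rate: the descent sanity check should hold even on a
  # 100-curve smoke corpus
  cfg <- network_config(seed = 3, learning_rate = 0.01)
  mt <- train_network(build_network(cfg), tr, va, epochs = 5)
  expect_identical(nrow(mt$history), 5L)
  expect_true(all(is.finite(mt$history$train_loss)))
  expect_true(all(is.finite(mt$history$val_loss)))
  expect_lte(mt$history$train_loss[5], mt$history$train_loss[1])
  expect_true(mt$trained)

  # bit-identical rerun under the same seeds
  mt2 <- train_network(build_network(cfg), tr, va, epochs = 5)
  expect_identical(mt$history$val_loss, mt2$history$val_loss)
  expect_identical(predict_matrix(mt, tr$curves[1:2, ]),
                   predict_matrix(mt2, tr$curves[1:2, ]))
})

test_that("predictions are canonically sorted with amplitudes co-moved", {
  m <- tiny_model()
  x <- build_dataset(8, time_grid(), seed = 55)
  p <- predict_matrix(m, x$curves)
  expect_true(all(p[, 2:4] - p[, 1:3] >= 0))
  expect_true(all(p > 0 & p < 1))
  raw <- thermospec:::cnn_predict_cpp(m$weights, x$curves)
  for (i in 1:8) {
    o <- order(raw[i, 1:4])
    expect_identical(p[i, ], c(raw[i, o], raw[i, 4 + o]))
  }
  expect_error(predict_matrix(m, matrix(0, 2, 100)), "length")
})

test_that("model state round-trips through disk", {
  m <- tiny_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  x <- build_dataset(2, time_grid(), seed = 77)$curves
  expect_identical(predict_matrix(m2, x), predict_matrix(m, x))
  cfg <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_identical(cfg$w_tau, 0.2)
})
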