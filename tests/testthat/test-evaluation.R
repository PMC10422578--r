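test_that("component MSE matches a hand-coded oracle", {
  y <- matrix(runif(48), 6, 8)
  perfect <- component_mse(y, y)
  expect_identical(perfect$tau, rep(0, 4))
  expect_identical(perfect$amp, rep(0, 4))

  # single pair, first tau off by 0.1
  p <- y[1, , drop = FALSE]; q <- p; q[1] <- q[1] + 0.1
  single <- component_mse(q, p)
  expect_equal(single$tau, c(0.01, 0, 0, 0), tolerance = 1e-15)
  expect_identical(single$amp, rep(0, 4))

  set.seed(4)
  for (rep in 1:5) {
    pred <- matrix(runif(64), 8, 8); truth <- matrix(runif(64), 8, 8)
    cm <- component_mse(pred, truth)
    for (j in 1:4) {
      expect_equal(cm$tau[j], mean((pred[, j] - truth[, j])^2),
                   tolerance = 1e-12)
      expect_equal(cm$amp[j], mean((pred[, j + 4] - truth[, j + 4])^2),
                   tolerance = 1e-12)
    }
    # the means equal the average of the per-component values
    expect_equal(cm$tau_mean, mean(cm$tau), tolerance = 1e-12)
    expect_equal(cm$amp_mean, mean(cm$amp), tolerance = 1e-12)
  }
  expect_error(component_mse(matrix(0, 2, 8), matrix(0, 3, 8)), "dimensions")
})

test_that("curve MSE is zero for perfect parameters and scales quadratically", {
  g <- time_grid(256)
  d <- build_dataset(10, g, seed = 31)
  expect_equal(curve_mse(d$targets, d$curves, g), 0, tolerance = 1e-20)

  # doubling an amplitude error quadruples the curve MSE (linearity of the
  # model in the amplitudes)
  p1 <- d$targets; p1[, 5] <- p1[, 5] + 0.05
  p2 <- d$targets; p2[, 5] <- p2[, 5] + 0.10
  m1 <- curve_mse(p1, d$curves, g); m2 <- curve_mse(p2, d$curves, g)
  expect_equal(m2 / m1, 4, tolerance = 1e-9)
  expect_error(curve_mse(d$targets, d$curves[, 1:100], g), "grid")
})

test_that("evaluation reports carry consistent means and the noise tag", {
  m <- tiny_model()
  d <- build_dataset(60, time_grid(), seed = 41)
  r <- evaluate_model(m, d)
  expect_s3_class(r, "evaluation_report")
  expect_equal(r$tau_mean, mean(r$tau_mse), tolerance = 1e-12)
  expect_equal(r$amp_mean, mean(r$amp_mse), tolerance = 1e-12)
  expect_true(all(c(r$tau_mse, r$amp_mse, r$curve_mse) >= 0))
  expect_identical(r$variance, 0)
  expect_identical(r$n_test, 60L)
})

test_that("noise sweep reproduces the clean protocol at variance zero", {
  m <- tiny_model()
  d <- build_dataset(40, time_grid(), seed = 43)
  sweep <- noise_sweep(m, d, variances = c(0, 1e-4, 5e-3), seed = 9)
  expect_length(sweep, 3)
  clean <- evaluate_model(m, d)
  expect_identical(sweep[[1]]$tau_mse, clean$tau_mse)
  expect_identical(sweep[[1]]$curve_mse, clean$curve_mse)
  expect_identical(vapply(sweep, `[[`, 0, "variance"), c(0, 1e-4, 5e-3))
  # same base seed -> identical sweep
  sweep2 <- noise_sweep(m, d, variances = c(0, 1e-4, 5e-3), seed = 9)
  expect_identical(sweep2[[3]]$tau_mse, sweep[[3]]$tau_mse)
})

test_that("report rendering produces the table layout and survives CSV", {
  m <- tiny_model()
  d <- build_dataset(30, time_grid(), seed = 47)
  one <- render_report(evaluate_model(m, d))
  rows <- attr(one, "data")
  expect_identical(nrow(rows), 5L)
  expect_identical(rows$component, c("1", "2", "3", "4", "mean"))

  sweep <- noise_sweep(m, d, seed = 2)   # default six variances
  f <- withr::local_tempfile(fileext = ".csv")
  txt <- render_report(sweep, file = f)
  tab <- attr(txt, "data")
  expect_identical(nrow(tab), 30L)       # 6 groups of 5 rows
  back <- read_report_csv(f)
  expect_equal(back$tau_mse, tab$tau_mse, tolerance = 1e-12)
  expect_identical(back$component, tab$component)
})
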