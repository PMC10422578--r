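test_that("evaluate_curve matches hand-computed multi-exponential values", {
  # four identical components: T(t) = 1 - e^{-t} at t = 1
  s <- exp_spectrum(rep(1, 4), rep(0.25, 4))
  g <- time_grid(8, t_end = 1)
  expect_equal(evaluate_curve(s, g)$values[8], 1 - exp(-1), tolerance = 1e-12)

  # the curve vanishes as t -> 0+
  g_fine <- time_grid(1024, t_end = 1)
  expect_lt(evaluate_curve(s, g_fine)$values[1], 1e-3)

  # component-wise direct summation on arbitrary parameters
  s2 <- exp_spectrum(c(0.02, 0.1, 0.4, 0.9), c(0.3, 0.1, 0.7, 0.2),
                     normalized = TRUE)
  t5 <- g_fine$samples[500]
  expect_equal(evaluate_curve(s2, g_fine)$values[500],
               sum(s2$amp * (1 - exp(-t5 / s2$tau))), tolerance = 1e-14)
})

test_that("quasi-steady-state value equals the sum of amplitudes", {
  # skin-like spectrum spanning seconds to hundreds of seconds
  s <- exp_spectrum(table4_healthy$tau, table4_healthy$amp)
  far <- time_grid(4, t_end = 200 * max(s$tau))
  expect_equal(evaluate_curve(s, far)$values[4], sum(s$amp),
               tolerance = 1e-9)
  expect_equal(sum(s$amp), 4.2562101, tolerance = 1e-7)
  # at the six-minute mark the slowest component has not fully settled
  g6min <- time_grid(16, t_end = 3600)
  expect_equal(evaluate_curve(s, g6min)$values[16], 4.2562101,
               tolerance = 1e-6)
})

test_that("noiseless curves are non-decreasing and bounded by the asymptote", {
  set.seed(42)
  g <- time_grid(256)
  for (i in 1:20) {
    s <- sample_spectrum()
    v <- evaluate_curve(s, g)$values
    expect_true(all(diff(v) >= 0))
    expect_true(all(v <= sum(s$amp)))
  }
})

test_that("spectrum constructor enforces the domain invariants", {
  expect_error(exp_spectrum(c(1, -1, 1, 1), rep(0.2, 4)), "positive")
  expect_error(exp_spectrum(c(1, 0, 1, 1), rep(0.2, 4)), "positive")
  expect_error(exp_spectrum(rep(1, 4), c(-0.1, 0.2, 0.2, 0.2)),
               "non-negative")
  expect_error(exp_spectrum(rep(1, 4), rep(0.2, 3)), "equal")
  expect_warning(exp_spectrum(c(0.1, 0.2, 0.3, 1.4), rep(0.2, 4),
                              normalized = TRUE), "outside")
})

test_that("time grid is dense at early times with monotone spacing", {
  g <- time_grid(1024, t_end = 1)
  expect_length(g$samples, 1024)
  expect_identical(g$samples[1024], 1)
  expect_gt(g$samples[1], 0)
  expect_true(all(diff(g$samples) > 0))
  expect_true(all(diff(diff(g$samples)) > 0))  # spacing grows with index
  expect_gte(sum(g$samples <= 0.1), 512)

  g2 <- time_grid(2, t_end = 5)
  expect_length(g2$samples, 2)
  expect_identical(g2$samples[2], 5)

  expect_error(time_grid(1), ">= 2")
  expect_error(time_grid(100, t_end = 0), "positive")
  expect_error(time_grid(100, density = -1), "positive")
})

test_that("sort_components canonicalizes without changing the curve", {
  s <- exp_spectrum(c(0.5, 0.1, 0.9, 0.3), c(0.11, 0.22, 0.33, 0.44),
                    normalized = TRUE)
  expect_equal(s$tau, c(0.1, 0.3, 0.5, 0.9))
  expect_equal(s$amp, c(0.22, 0.44, 0.11, 0.33))
  expect_identical(sort_components(s), s)  # idempotent

  # permutation invariance of the forward model
  g <- time_grid(128)
  s_perm <- structure(list(tau = c(0.9, 0.1, 0.5, 0.3),
                           amp = c(0.33, 0.22, 0.11, 0.44),
                           normalized = TRUE), class = "exp_spectrum")
  expect_equal(evaluate_curve(sort_components(s_perm), g)$values,
               evaluate_curve(s_perm, g)$values, tolerance = 1e-15)
})

test_that("normalize and rescale are exact inverses", {
  tr <- scaling_transform(360, 5.5)
  s <- exp_spectrum(c(1.9, 19, 113, 230), c(1.35, 1.15, 0.95, 0.81))
  n <- normalize_spectrum(s, tr)
  expect_true(n$normalized)
  expect_equal(n$tau, s$tau / 360, tolerance = 1e-15)
  # hand arithmetic: 230.25365 / 360
  n4 <- normalize_spectrum(exp_spectrum(table4_healthy$tau,
                                        table4_healthy$amp),
                           scaling_transform(360, 5.5))
  expect_equal(n4$tau[4], 0.63959347222222, tolerance = 1e-9)

  r <- rescale_spectrum(n, tr)
  expect_false(r$normalized)
  expect_equal(r$tau, s$tau, tolerance = 1e-12)
  expect_equal(r$amp, s$amp, tolerance = 1e-12)

  ident <- scaling_transform(1, 1)
  s_n <- exp_spectrum(c(0.1, 0.2, 0.3, 0.4), rep(0.5, 4), normalized = TRUE)
  expect_equal(rescale_spectrum(s_n, ident)$tau, s_n$tau)
  expect_error(scaling_transform(0, 1), "positive")
})

test_that("evaluating normalized then rescaling equals the physical curve", {
  tr <- scaling_transform(420, 6.2)
  s_phys <- exp_spectrum(c(2.1, 21, 120, 260), c(1.2, 1.0, 0.9, 0.7))
  s_norm <- normalize_spectrum(s_phys, tr)
  g_norm <- time_grid(512, t_end = 1)
  g_phys <- time_grid(512, t_end = tr$t_scale)
  v_norm <- evaluate_curve(s_norm, g_norm)$values
  v_phys <- evaluate_curve(s_phys, g_phys)$values
  expect_equal(v_norm * tr$temp_scale, v_phys, tolerance = 1e-9)
})

test_that("spectrum JSON and curve CSV serialization round-trip", {
  s <- exp_spectrum(c(0.01, 0.05, 0.2, 0.8), c(0.4, 0.3, 0.5, 0.6),
                    normalized = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  write_spectrum_json(s, f)
  s2 <- read_spectrum_json(f)
  expect_equal(s2$tau, s$tau, tolerance = 1e-15)
  expect_equal(s2$amp, s$amp, tolerance = 1e-15)
  expect_true(s2$normalized)

  sp <- exp_spectrum(table4_healthy$tau, table4_healthy$amp)
  write_spectrum_json(sp, f)
  expect_false(read_spectrum_json(f)$normalized)

  cf <- withr::local_tempfile(fileext = ".csv")
  g <- time_grid(64, t_end = 360)
  write_curve_csv(evaluate_curve(sp, g), cf)
  m <- read_measurement(cf)
  expect_equal(m$times, g$samples, tolerance = 1e-12)
})
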