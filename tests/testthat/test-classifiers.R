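test_that("coefficient of variation uses the population convention", {
  expect_equal(coefficient_of_variation(c(1, 1, 1, 3)), sqrt(0.75) / 1.5)
  expect_identical(coefficient_of_variation(rep(2.5, 10)), 0)
  x <- rlnorm(100)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
  expect_error(coefficient_of_variation(1), "2 samples")
})

test_that("spectral verdict separates ramps, tones and noise", {
  t <- seq(0, 200, by = 0.1)
  expect_identical(spectral_verdict(seq_len(500) * 0.3), "monotonic")
  expect_identical(spectral_verdict(sin(2 * pi * t / 7)), "discrete-peaks")
  # harmonic-rich periodic signal still counts as discrete peaks
  expect_identical(spectral_verdict(sin(2 * pi * t / 7)^3 +
                                      0.5 * cos(2 * pi * t / 3.5)),
                   "discrete-peaks")
  set.seed(8)
  expect_identical(spectral_verdict(rnorm(1e5)), "broadband")
})

test_that("decision rules implement the indicator thresholds", {
  dl <- planktonchaos:::decide_label
  expect_identical(dl(5e-5, 0.5, "discrete-peaks", 0.01), "extinct")
  expect_identical(dl(1, 1e-4, "broadband", 0.01), "stationary")
  expect_identical(dl(1, 0.5, "monotonic", 0.01), "stationary")
  expect_identical(dl(1, 0.5, "discrete-peaks", 1e-4), "periodic")
  expect_identical(dl(1, 0.1, "broadband", 0.01), "chaotic")
})

test_that("Wolf map estimate matches the tangent-space oracle on the logistic map", {
  lam4 <- lyapunov_wolf_map(function(x) 4 * x * (1 - x), 0.2)
  expect_equal(lam4, log(2), tolerance = 0.01)
  expect_equal(lam4, benettin_logistic(4), tolerance = 0.01)
  # period-2 window is contracting
  expect_lt(lyapunov_wolf_map(function(x) 3.2 * x * (1 - x), 0.2,
                              n_iter = 2e4), 0)
  for (r in c(3.6, 3.8)) {
    lam <- lyapunov_wolf_map(function(x) r * x * (1 - x), 0.2)
    expect_equal(lam, benettin_logistic(r), tolerance = 0.05 * abs(lam) + 0.005)
  }
})

test_that("Wolf flow estimate reproduces the Lorenz exponent", {
  f <- planktonchaos:::lorenz_field()
  lam <- lyapunov_wolf_flow(f, c(1, 1, 1), dt = 0.01, n_steps = 6e4,
                            burn_in = 5e3)
  expect_equal(lam, 0.906, tolerance = 0.05 * 0.906)
  expect_equal(lam, benettin_lorenz(n = 1e5), tolerance = 0.05 * 0.906)
})

test_that("a trajectory at a fixed point gets a nonpositive exponent", {
  lam <- foodweb_lyapunov(preset_config("ES"), seasonal_params(A_y = 0),
                          transient_years = 10, measure_years = 20)
  expect_lte(lam, 0)
})

test_that("classify_series labels canonical series correctly", {
  s <- sine_series(period = 200, amplitude = 2, offset = 10, n = 5e3)
  cl <- classify_series(s$values)
  expect_identical(cl$label, "periodic")
  expect_identical(cl$spectral_verdict, "discrete-peaks")
  expect_identical(classify_series(rep(4, 100))$label, "stationary")
  # extinction rule engages only when a threshold is given
  low <- abs(sin(seq(0, 20, by = 0.01))) * 1e-3 + 5e-5
  expect_identical(classify_series(low, extinct_threshold = 1e-4)$label,
                   "extinct")
})

test_that("classification of trajectories matches the regime of the forcing", {
  tr <- integrate_foodweb(preset_config("ES"), seasonal_params(A_y = 2),
                          years = 20)
  cl <- classify_trajectory(tr, lambda_measure_years = 30)
  expect_identical(cl$label, "periodic")
  expect_gt(cl$cv, 1e-3)
  expect_lt(cl$lambda_max, 1e-3)
})
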