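test_that("seasonal temperature follows the annual cosine", {
  sp <- seasonal_params(T_bar = 15, A_y = 5)
  expect_equal(seasonal_temperature(0, sp), 10)
  expect_equal(seasonal_temperature(182.5, sp), 20)
  expect_equal(seasonal_temperature(c(3, 77, 200), seasonal_params(A_y = 0)),
               rep(15, 3))
  # periodicity to machine precision
  t <- seq(0, 700, by = 13.7)
  expect_equal(seasonal_temperature(t, sp),
               seasonal_temperature(t + 365, sp), tolerance = 1e-12)
})

test_that("parameter constructors validate their domains", {
  expect_error(seasonal_params(A_y = -1), "A_y")
  expect_error(seasonal_params(tau_y = 0), "tau_y")
  expect_error(ou_params(tau = -5), "tau")
  expect_error(ou_params(tau = 10, D = -1), "D")
  expect_error(simulate_ou(ou_params(tau = 10), dt = 0, n_steps = 10), "dt")
})

test_that("OU simulation starts at zero and is exact in its moments", {
  op <- ou_params(tau = 30, D = 2 * 1e-2 / 30, seed = 7)
  x <- simulate_ou(op, dt = 0.5, n_steps = 2e5)
  expect_identical(x[1], 0)
  v_target <- op$D * op$tau / 2
  burn <- 2000
  xs <- x[-seq_len(burn)]
  n_eff <- length(xs) * 0.5 / (2 * op$tau)  # decorrelation-adjusted size
  expect_lt(abs(mean(xs)), 3 * sqrt(v_target / n_eff))
  expect_lt(abs(mean(xs^2) - v_target), 3 * v_target * sqrt(2 / n_eff))
  # noiseless process stays at zero
  expect_identical(simulate_ou(ou_params(tau = 30, D = 0), 0.5, 100),
                   numeric(101))
})

test_that("OU autocorrelation decays as exp(-lag/tau)", {
  op <- ou_params(tau = 30, D = 2 * 1e-2 / 30, seed = 12)
  dt <- 1
  x <- simulate_ou(op, dt = dt, n_steps = 3e5)[-(1:500)]
  lag <- round(op$tau / dt)
  r <- stats::cor(x[-(1:lag)], x[seq_len(length(x) - lag)])
  expect_equal(r, exp(-1), tolerance = 0.08)
})

test_that("OU stationary variance does not depend on the step size", {
  # exact transition density: no discretization bias even at coarse dt
  for (dt in c(0.1, 5, 40)) {
    x <- simulate_ou(ou_params(tau = 30, D = 2e-2 / 30, seed = 99), dt,
                     n_steps = ceiling(3e5 / dt))
    xs <- x[-seq_len(ceiling(200 / dt))]
    n_eff <- length(xs) * dt / (2 * 30) + 1
    expect_lt(abs(mean(xs^2) - 0.01), 4 * 0.01 * sqrt(2 / n_eff))
  }
})

test_that("same seed reproduces the OU path bit for bit", {
  op <- ou_params(tau = 10, seed = 3)
  expect_identical(simulate_ou(op, 0.1, 1000), simulate_ou(op, 0.1, 1000))
  expect_false(isTRUE(all.equal(simulate_ou(op, 0.1, 1000),
                                simulate_ou(op, 0.1, 1000, seed = 4))))
})

test_that("stochastic temperature is the sum of its components", {
  times <- seq(0, 730, by = 0.5)
  sp <- seasonal_params(A_y = 5)
  ts1 <- stochastic_temperature(times, sp, ou_params(tau = 30, seed = 5))
  expect_identical(ts1$total, ts1$det + ts1$noise)
  expect_identical(ts1$noise[1], 0)
  # zero-noise degenerate case collapses onto the deterministic cycle
  ts0 <- stochastic_temperature(times, sp, ou_params(tau = 30, D = 0))
  expect_identical(ts0$total, ts0$det)
  tsc <- stochastic_temperature(times, seasonal_params(A_y = 0),
                                ou_params(tau = 30, D = 0))
  expect_identical(unique(tsc$total), 15)
  expect_error(stochastic_temperature(c(0, 1, 3), sp), "uniform")
  expect_error(stochastic_temperature(c(0, -1, -2), sp), "increasing")
})

test_that("ensemble mean of the total temperature converges to the cycle", {
  times <- seq(0, 365, by = 1)
  sp <- seasonal_params(A_y = 5)
  tot <- rowMeans(vapply(1:300, function(k)
    stochastic_temperature(times, sp, ou_params(tau = 10, seed = k))$total,
    numeric(length(times))))
  se <- sqrt(0.01 / 300)
  expect_lt(max(abs(tot - seasonal_temperature(times, sp))), 5 * se)
})

test_that("temperature series round-trips through CSV", {
  ts1 <- stochastic_temperature(seq(0, 10, by = 0.5), seasonal_params(A_y = 2),
                                ou_params(tau = 5, seed = 1))
  f <- tempfile(fileext = ".csv")
  write_temperature_csv(ts1, f)
  back <- utils::read.csv(f)
  expect_named(back, c("time_days", "T_det", "T_noise", "T_total"))
  expect_equal(back$T_total, ts1$total, tolerance = 1e-12)
  unlink(f)
})
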