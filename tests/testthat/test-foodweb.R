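test_that("Q10 factor matches its defining examples", {
  expect_identical(q10_factor(10, 2, 10), 1)
  expect_identical(q10_factor(20, 2, 10), 2)
  expect_identical(q10_factor(20, 2.95, 10), 2.95)
  expect_error(q10_factor(15, -1), "Q10")
  # strictly increasing in T for Q10 > 1
  expect_true(all(diff(q10_factor(seq(0, 30, 0.5), 2)) > 0))
})

test_that("gross primary production factorizes and vanishes at its zeros", {
  cfg <- foodweb_config()
  expect_identical(gross_primary_production(10, 0.1, 15, foodweb_config(f_I = 0)), 0)
  expect_identical(gross_primary_production(10, 0, 15, cfg), 0)
  expect_identical(gross_primary_production(0, 0.1, 15, cfg), 0)
  # at T_ref, saturating nutrient, full light: r_max * P
  expect_equal(gross_primary_production(10, 1e6, 10, cfg),
               cfg$r_max[1] * 10, tolerance = 1e-4)
})

test_that("the vector field conserves phosphorus-equivalent mass exactly", {
  cfg <- foodweb_config()
  set.seed(1)
  for (k in 1:20) {
    st <- c(runif(6, 0, 50), runif(1, 0, 0.2))
    names(st) <- planktonchaos:::foodweb_pools()
    d <- foodweb_derivatives(st, runif(1, 0, 30), cfg)
    expect_lt(abs(cfg$q * sum(d[1:6]) + d[7]), 1e-12)
  }
  z <- stats::setNames(numeric(7), planktonchaos:::foodweb_pools())
  expect_identical(unname(foodweb_derivatives(z, 15, cfg)), numeric(7))
})

test_that("compiled and reference derivatives agree", {
  cfg <- foodweb_config()
  set.seed(2)
  for (k in 1:10) {
    st <- c(runif(6, 0, 80), runif(1, 0, 0.2))
    names(st) <- planktonchaos:::foodweb_pools()
    T <- runif(1, 0, 30)
    expect_equal(foodweb_derivatives(st, T, cfg, use_compiled = TRUE),
                 foodweb_derivatives(st, T, cfg, use_compiled = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("metabolic fluxes increase with temperature", {
  cfg <- foodweb_config()
  st <- c(P1 = 10, P2 = 10, Z1 = 5, Z2 = 5, B = 5, D = 10, N = 0.05)
  gpp <- vapply(c(5, 10, 15, 20, 25),
                function(T) gross_primary_production(10, 0.05, T, cfg),
                numeric(1))
  expect_true(all(diff(gpp) > 0))
})

test_that("a lone producer grows at r_max minus its losses initially", {
  cfg <- foodweb_config()
  st <- c(P1 = 1, P2 = 0, Z1 = 0, Z2 = 0, B = 0, D = 0, N = 1e6)
  d <- foodweb_derivatives(st, cfg$T_ref, cfg)
  expect_equal(d[["P1"]],
               cfg$r_max[1] - cfg$s_p[1] - cfg$x_p[1] - cfg$m_p[1],
               tolerance = 1e-4)
})

test_that("integration reaches the ES fixed point and conserves mass", {
  tr <- integrate_foodweb(preset_config("ES"), seasonal_params(A_y = 0),
                          years = 20)
  w <- trajectory_window(tr, 10)
  cvs <- apply(w$state[, 1:5], 2, function(s) sd(s) / mean(s))
  expect_lt(max(cvs), 1e-3)
  m <- total_mass(tr)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-6)
  expect_true(all(tr$state >= 0))
})

test_that("zero initial biomass stays zero", {
  cfg <- foodweb_config(init_biomass = c(P1 = 0, P2 = 0, Z1 = 0, Z2 = 0,
                                         B = 0, D = 0))
  tr <- integrate_foodweb(cfg, seasonal_params(A_y = 0), years = 1)
  expect_identical(max(tr$state[, 1:6]), 0)
  expect_identical(min(tr$state[, "N"]), cfg$PO4_0)
})

test_that("integration is deterministic given config and forcing", {
  cfg <- preset_config("EP")
  t1 <- integrate_foodweb(cfg, seasonal_params(A_y = 3), years = 3)
  t2 <- integrate_foodweb(cfg, seasonal_params(A_y = 3), years = 3)
  expect_identical(t1$state, t2$state)
})

test_that("fixed-step solution matches an adaptive reference integrator", {
  skip_if_not_installed("deSolve")
  cfg <- preset_config("ES")
  sp <- seasonal_params(A_y = 2)
  f <- function(t, y, parms) {
    list(as.numeric(foodweb_derivatives(y, seasonal_temperature(t, sp), cfg)))
  }
  y0 <- planktonchaos:::foodweb_initial_state(cfg)
  ref <- deSolve::lsoda(y0, seq(0, 365, by = 73), f, NULL,
                        rtol = 1e-10, atol = 1e-10)
  tr <- integrate_foodweb(cfg, sp, years = 1)
  idx <- match(seq(0, 365, by = 73), round(tr$times, 6))
  expect_equal(unname(tr$state[idx, ]), unname(ref[, -1]), tolerance = 1e-5)
})

test_that("presets express their endogenous regimes", {
  # stationary / periodic / chaotic structure of the calibrated presets
  es <- classify_trajectory(integrate_foodweb(preset_config("ES"),
                                              seasonal_params(A_y = 0)),
                            lambda_measure_years = 30)
  expect_identical(es$label, "stationary")
  ep <- classify_trajectory(integrate_foodweb(preset_config("EP"),
                                              seasonal_params(A_y = 0)),
                            lambda_measure_years = 30)
  expect_identical(ep$label, "periodic")
  ec <- classify_trajectory(integrate_foodweb(preset_config("EC"),
                                              seasonal_params(A_y = 0)),
                            lambda_measure_years = 60)
  expect_identical(ec$label, "chaotic")
  expect_gt(ec$lambda_max, 1e-3)
  expect_error(preset_config("XX"))
})
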