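test_that("ordinal pattern follows the ascending-order convention", {
  expect_identical(ordinal_pattern(c(4.2, 3.1, 5.6)), c(2L, 1L, 3L))
  expect_identical(ordinal_pattern(1:6), 1:6)
  expect_identical(ordinal_pattern(c(5, 5, 1)), c(3L, 1L, 2L))  # stable ties
  w <- c(0.3, -1.2, 2.2, 0.9)
  expect_identical(ordinal_pattern(w), ordinal_pattern(exp(w)))
})

test_that("ordinal probabilities count windows and sum to one", {
  set.seed(3)
  x <- rnorm(500)
  for (d in 3:5) for (eps in c(1L, 3L, 7L)) {
    dist <- ordinal_probabilities(x, d = d, eps = eps)
    expect_identical(dist$n_windows, length(x) - (d - 1L) * eps)
    expect_equal(sum(dist$p), 1)
    expect_lte(length(dist$p), factorial(d))
  }
  expect_error(ordinal_probabilities(1:5, d = 6), "too short")
  mono <- ordinal_probabilities(seq_len(100), d = 4)
  expect_identical(mono$p, 1)
})

test_that("iid noise approaches the uniform pattern distribution", {
  set.seed(4)
  dist <- ordinal_probabilities(runif(1e5), d = 3)
  expect_identical(length(dist$p), 6L)
  expect_lt(max(abs(dist$p - 1 / 6)), 0.01)
})

test_that("entropy and complexity identities hold", {
  M <- 24
  expect_identical(permutation_entropy(c(1, rep(0, M - 1))), 0)
  expect_equal(permutation_entropy(rep(1 / M, M)), 1)
  expect_equal(permutation_entropy(c(0.5, 0.5), M = 6), log(2) / log(6))
  expect_equal(statistical_complexity(rep(1 / M, M)), 0)
  expect_identical(statistical_complexity(c(1, rep(0, M - 1))), 0)
  # 0 log 0 convention: padding with zeros changes nothing
  p <- c(0.4, 0.35, 0.25)
  expect_equal(permutation_entropy(c(p, 0, 0), M = 5),
               permutation_entropy(p, M = 5))
})

test_that("entropy and complexity match the naive reference implementation", {
  set.seed(5)
  worst <- 0
  for (k in 1:20) {
    d <- sample(3:6, 1)
    eps <- sample(1:4, 1)
    x <- switch(1 + k %% 3, rnorm(800), cumsum(rnorm(800)),
                sin(seq_len(800) / 7) + rnorm(800, sd = 0.3))
    dist <- ordinal_probabilities(x, d = d, eps = eps)
    ref <- naive_ordinal_stats(x, d, eps)
    worst <- max(worst, abs(permutation_entropy(dist) - ref$hs),
                 abs(statistical_complexity(dist) - ref$cjs))
    expect_equal(sort(dist$p, decreasing = TRUE), ref$p, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-6)
})

test_that("entropy and complexity are invariant under monotone transforms", {
  set.seed(6)
  x <- rnorm(2000)
  for (g in list(exp, function(v) v^3 + 2 * v, function(v) atan(v))) {
    d1 <- ordinal_probabilities(x, d = 4)
    d2 <- ordinal_probabilities(g(x), d = 4)
    expect_identical(permutation_entropy(d1), permutation_entropy(d2))
    expect_identical(statistical_complexity(d1), statistical_complexity(d2))
  }
})

test_that("brute-force statistical complexity agrees on a tiny alphabet", {
  # p = (0.75, 0.25), M = 2: evaluate the defining formula directly
  p <- c(0.75, 0.25)
  S <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  J <- S((p + 0.5) / 2) - S(p) / 2 - S(c(0.5, 0.5)) / 2
  Jmax <- -0.5 * (3 / 2 * log(3) - 2 * log(4) + log(2))
  expected <- J / Jmax * (S(p) / log(2))
  expect_equal(statistical_complexity(p), expected)
  expect_gt(expected, 0)
})

test_that("bound curves pinch to zero and contain random distributions", {
  for (M in c(6, 24)) {
    b <- complexity_bounds(M)
    ends <- bounds_at(b, c(0, 1))
    expect_lt(max(abs(unlist(ends[, c("CJS_min", "CJS_max")]))), 1e-6)
    set.seed(M)
    for (k in 1:500) {
      p <- random_prob(M)
      hs <- permutation_entropy(p, M = M)
      cj <- statistical_complexity(p, M = M)
      bd <- bounds_at(b, hs)
      expect_gte(cj, bd$CJS_min - 1e-3)  # interpolation slack on the lower arc
      expect_lte(cj, bd$CJS_max + 1e-9)
    }
  }
})

test_that("deseasonalization removes phase-locked structure and only that", {
  n_years <- 30
  t <- seq(0, 365 * n_years - 1, by = 1)
  sine <- 3 * cos(2 * pi * t / 365)
  expect_lt(max(abs(deseasonalize(sine, t))), 1e-10)
  set.seed(7)
  noise <- rnorm(length(t), sd = 0.5)
  res <- deseasonalize(sine + noise, t)
  # the per-phase mean absorbs 1/n_years of the noise variance
  expect_equal(var(res), (1 - 1 / n_years) * var(noise),
               tolerance = 0.02)
  expect_equal(var(res), var(noise), tolerance = 0.05)
  # idempotence: a second pass changes nothing
  expect_equal(deseasonalize(res, t), res, tolerance = 1e-12)
  expect_error(deseasonalize(sine[1:400], t[1:400]), "two full periods")
})

test_that("the causality plane separates the canonical signal classes", {
  b <- complexity_bounds(720)
  dl <- c(1:5, 8, 13, 21, 34)
  set.seed(9)
  cw <- cep_curve(rnorm(1e4), delays = dl, bounds = b)
  expect_true(all(cw$HS > 0.9))
  expect_true(all(cw$CJS < 0.1))
  expect_identical(detect_chaos_cep(cw)$verdict, "white-noise")
  ou <- noise_series("ou", n = 1e4, seed = 10, tau = 50)
  co <- cep_curve(ou$values, delays = dl, bounds = b)
  expect_identical(detect_chaos_cep(co)$verdict, "colored-noise")
  expect_true(any(co$HS < 0.95))  # intermediate entropy at short delays
  lg <- logistic_series(4, n = 1e4)
  cl <- cep_curve(lg$values, delays = dl, bounds = b)
  vd <- detect_chaos_cep(cl)
  expect_identical(vd$verdict, "chaotic")
  hit <- cl[cl$eps %in% vd$supporting_delays, ]
  expect_true(all(hit$HS >= 0.45 & hit$HS <= 0.70))
  expect_true(all(hit$CJS >= 0.95 * hit$CJS_max))
})

test_that("every computed point lies between the bound curves", {
  b <- complexity_bounds(720)
  set.seed(11)
  series <- list(rnorm(3000), cumsum(rnorm(3000)),
                 logistic_series(3.9, n = 3000)$values,
                 sin(seq_len(3000) / 11))
  for (s in series) {
    cv <- cep_curve(s, delays = c(1, 2, 5, 11), bounds = b)
    expect_true(all(cv$CJS <= cv$CJS_max + 1e-9))
    expect_true(all(cv$CJS >= cv$CJS_min - 1e-9))
  }
})
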