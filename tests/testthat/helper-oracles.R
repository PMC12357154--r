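# Independent brute-force oracles, deliberately naive: these share no code
# with the package implementations they check.

# ordinal-pattern statistics via order() + string keys, one window at a time
naive_ordinal_stats <- function(series, d, eps) {
  n_win <- length(series) - (d - 1) * eps
  keys <- character(n_win)
  for (t in seq_len(n_win)) {
    w <- series[t + (0:(d - 1)) * eps]
    keys[t] <- paste(order(w), collapse = "-")
  }
  p <- as.numeric(table(keys)) / n_win
  M <- factorial(d)
  S <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  hs <- S(p) / log(M)
  # Jensen-Shannon divergence to uniform, counting unobserved symbols
  mix <- c((p + 1 / M) / 2, rep(1 / (2 * M), M - length(p)))
  J <- S(mix) - S(p) / 2 - log(M) / 2
  Jmax <- -0.5 * ((M + 1) / M * log(M + 1) - 2 * log(2 * M) + log(M))
  list(hs = hs, cjs = J / Jmax * hs, p = sort(p, decreasing = TRUE))
}

# logistic-map Lyapunov exponent from the tangent map (derivative product)
benettin_logistic <- function(r, x0 = 0.2, n = 1e5, burn = 1000) {
  x <- x0
  for (k in seq_len(burn)) x <- r * x * (1 - x)
  s <- 0
  for (k in seq_len(n)) {
    s <- s + log(abs(r * (1 - 2 * x)))
    x <- r * x * (1 - x)
  }
  s / n
}

# Lorenz maximal exponent via Jacobian tangent-vector evolution (Benettin),
# RK4 on the coupled state + tangent system
benettin_lorenz <- function(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.005,
                            n = 2e5, burn = 2e4) {
  f <- function(u) {
    x <- u[1:3]; v <- u[4:6]
    c(sigma * (x[2] - x[1]),
      x[1] * (rho - x[3]) - x[2],
      x[1] * x[2] - beta * x[3],
      sigma * (v[2] - v[1]),
      (rho - x[3]) * v[1] - v[2] - x[1] * v[3],
      x[2] * v[1] + x[1] * v[2] - beta * v[3])
  }
  step <- function(u) {
    k1 <- f(u); k2 <- f(u + dt / 2 * k1); k3 <- f(u + dt / 2 * k2)
    k4 <- f(u + dt * k3)
    u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  u <- c(1, 1, 1, 1, 0, 0)
  for (k in seq_len(burn)) {
    u <- step(u)
    u[4:6] <- u[4:6] / sqrt(sum(u[4:6]^2))
  }
  s <- 0
  for (k in seq_len(n)) {
    u <- step(u)
    nv <- sqrt(sum(u[4:6]^2))
    s <- s + log(nv)
    u[4:6] <- u[4:6] / nv
  }
  s / (n * dt)
}

# period-2 orbit of the logistic map from the quartic fixed-point equation
logistic_period2 <- function(r) {
  disc <- sqrt((r - 3) * (r + 1))
  sort(c((r + 1 + disc) / (2 * r), (r + 1 - disc) / (2 * r)))
}

# random probability vector (flat Dirichlet)
random_prob <- function(M) {
  g <- stats::rexp(M)
  g / sum(g)
}
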