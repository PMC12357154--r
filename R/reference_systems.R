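new_labeled_series <- function(values, times, true_label, generator, params,
                               seed = NA_integer_) {
  structure(list(values = values, times = times, true_label = true_label,
                 generator = generator, params = params, seed = seed),
            class = "labeled_series")
}

#' @export
print.labeled_series <- function(x, ...) {
  cat(sprintf("Labeled series '%s' (%s): %d samples, label = %s\n",
              x$generator, paste(names(x$params), unlist(x$params),
                                 sep = "=", collapse = ", "),
              length(x$values), x$true_label))
  invisible(x)
}

#' Logistic-map series
#'
#' Iterates `x_{k+1} = r x_k (1 - x_k)` after a discarded burn-in. The
#' canonical dynamical classes: `r=2` converges to the fixed point
#' `1 - 1/r` (stationary), `r=3.2` to a period-2 orbit (periodic),
#' `r=4` is fully chaotic with Lyapunov exponent `log(2)` per iteration.
#'
#' @param r growth parameter in `(0, 4]`.
#' @param x0 initial condition in `(0, 1)`. Default 0.2.
#' @param n returned length. Default 1e4.
#' @param burn_in discarded iterations. Default 1000.
#' @return A `labeled_series` (times are iteration indices).
#' @export
logistic_series <- function(r, x0 = 0.2, n = 1e4, burn_in = 1000) {
  if (r <= 0 || r > 4) stop("'r' must be in (0, 4]", call. = FALSE)
  if (x0 <= 0 || x0 >= 1) stop("'x0' must be in (0, 1)", call. = FALSE)
  x <- x0
  for (k in seq_len(burn_in)) x <- r * x * (1 - x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    x <- r * x * (1 - x)
    out[k] <- x
  }
  label <- if (r <= 3) "stationary"
  else if (lyapunov_logistic_exact(r, x0) > 1e-3) "chaotic"
  else if (stats::sd(out[seq(max(1, n - 100), n)]) > 1e-8) "periodic"
  else "stationary"   # degenerate orbit captured by a fixed point
  new_labeled_series(out, seq_len(n), label, "logistic",
                     list(r = r, x0 = x0, burn_in = burn_in))
}

# tangent-space (derivative-product) exponent; used only for labeling
lyapunov_logistic_exact <- function(r, x0, n = 5e4, burn_in = 1000) {
  x <- x0
  for (k in seq_len(burn_in)) x <- r * x * (1 - x)
  s <- 0
  for (k in seq_len(n)) {
    s <- s + log(abs(r * (1 - 2 * x)))
    x <- r * x * (1 - x)
  }
  s / n
}

lorenz_field <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  function(x) c(sigma * (x[2] - x[1]),
                x[1] * (rho - x[3]) - x[2],
                x[1] * x[2] - beta * x[3])
}

#' Lorenz-system series
#'
#' Fixed-step RK4 integration of the Lorenz flow; the returned series is
#' the `x` coordinate. At the classical parameters (10, 28, 8/3) the flow
#' is chaotic with maximal Lyapunov exponent ~0.906; for `rho < 1` the
#' origin is globally stable and the label is stationary.
#'
#' @param sigma,rho,beta Lorenz parameters. Defaults 10, 28, 8/3.
#' @param dt integration/sampling step. Default 0.01.
#' @param n returned samples. Default 1e4.
#' @param burn_in discarded steps. Default 1000.
#' @param x0 initial state. Default `c(1, 1, 1)`.
#' @return A `labeled_series`.
#' @export
lorenz_series <- function(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.01,
                          n = 1e4, burn_in = 1000, x0 = c(1, 1, 1)) {
  f <- lorenz_field(sigma, rho, beta)
  x <- x0
  for (k in seq_len(burn_in)) x <- rk4_step_r(f, x, dt)
  out <- numeric(n)
  for (k in seq_len(n)) {
    x <- rk4_step_r(f, x, dt)
    if (!all(is.finite(x))) stop("Lorenz integration diverged", call. = FALSE)
    out[k] <- x[1]
  }
  label <- if (rho < 1) "stationary" else if (rho >= 24.74) "chaotic"
  else "periodic"
  new_labeled_series(out, seq_len(n) * dt, label, "lorenz",
                     list(sigma = sigma, rho = rho, beta = beta, dt = dt))
}

#' Stochastic benchmark series
#'
#' White Gaussian noise or an Ornstein-Uhlenbeck (red noise) realization,
#' labeled accordingly.
#'
#' @param kind `"white"` or `"ou"`.
#' @param n samples. Default 1e4.
#' @param seed RNG seed. Default 1.
#' @param sd white-noise standard deviation. Default 1.
#' @param tau OU correlation time in samples. Default 50.
#' @param variance OU stationary variance. Default 1.
#' @return A `labeled_series`.
#' @export
noise_series <- function(kind = c("white", "ou"), n = 1e4, seed = 1L,
                         sd = 1, tau = 50, variance = 1) {
  kind <- match.arg(kind)
  if (kind == "white") {
    set.seed(seed)
    v <- stats::rnorm(n, sd = sd)
    new_labeled_series(v, seq_len(n), "white-noise", "white",
                       list(sd = sd), seed)
  } else {
    op <- ou_params(tau = tau, D = 2 * variance / tau, seed = seed)
    v <- simulate_ou(op, dt = 1, n_steps = n)[-1L]
    new_labeled_series(v, seq_len(n), "colored-noise", "ou",
                       list(tau = tau, variance = variance), seed)
  }
}

#' Sinusoidal benchmark series
#'
#' @param period period in samples. Default 365.
#' @param amplitude amplitude. Default 1.
#' @param offset additive offset (keeps the mean away from zero so the CV
#'   indicator is defined). Default 10.
#' @param n samples. Default 1e4.
#' @param phase phase (radians). Default 0.
#' @return A `labeled_series` labeled `"periodic"`.
#' @export
sine_series <- function(period = 365, amplitude = 1, offset = 10, n = 1e4,
                        phase = 0) {
  v <- offset + amplitude * sin(2 * pi * seq_len(n) / period + phase)
  new_labeled_series(v, seq_len(n), "periodic", "sine",
                     list(period = period, amplitude = amplitude,
                          offset = offset))
}

#' Deterministic signal plus noise
#'
#' Adds a noise series to a base series at a prescribed signal-to-noise
#' ratio (variance ratio). The label is the base's label suffixed with
#' `"+noise"`.
#'
#' @param base a `labeled_series` (the deterministic component).
#' @param noise a `labeled_series` (the stochastic component), at least as
#'   long as `base`.
#' @param snr variance ratio var(base)/var(noise-after-scaling). Default 100.
#' @return A `labeled_series`.
#' @export
mixture_series <- function(base, noise, snr = 100) {
  stopifnot(inherits(base, "labeled_series"), inherits(noise, "labeled_series"))
  nb <- length(base$values)
  if (length(noise$values) < nb) stop("noise shorter than base", call. = FALSE)
  nz <- noise$values[seq_len(nb)]
  scale <- sqrt(stats::var(base$values) / (snr * stats::var(nz)))
  new_labeled_series(base$values + scale * nz, base$times,
                     paste0(base$true_label, "+noise"), "mixture",
                     list(base = base$generator, noise = noise$generator,
                          snr = snr))
}

#' Labeled reference suite
#'
#' Builds the ground-truth test surface for the classifier stages: >= 30
#' instances spanning white noise, colored (OU) noise, sinusoids, logistic
#' chaos (clean and noise-contaminated), logistic periodic/stationary
#' regimes and Lorenz chaos. Each instance records which detector is
#' expected to recognize it (`"cep"` for the ordinal machinery, `"indicators"`
#' for the CV/spectrum/Lyapunov classifier) and the expected verdict.
#'
#' @param seed master seed; instance seeds are derived deterministically.
#' @param n series length per instance. Default 1e4.
#' @return Data-frame-like list of instances, each with `series`,
#'   `detector`, `expected`.
#' @export
reference_suite <- function(seed = 1L, n = 1e4) {
  inst <- list()
  add <- function(series, detector, expected)
    inst[[length(inst) + 1L]] <<- list(series = series, detector = detector,
                                       expected = expected)
  for (k in 1:8)
    add(noise_series("white", n = n, seed = seed * 100L + k),
        "cep", "white-noise")
  for (k in 1:8)
    add(noise_series("ou", n = n, seed = seed * 200L + k, tau = 50),
        "cep", "colored-noise")
  for (k in 1:6)
    add(sine_series(period = 300 + 25 * k, amplitude = 1 + 0.2 * k, n = n),
        "indicators", "periodic")
  for (k in 1:6)
    add(logistic_series(4, x0 = 0.07 + 0.13 * k, n = n), "cep", "chaotic")
  for (k in 1:2)
    add(mixture_series(logistic_series(4, x0 = 0.17 + 0.1 * k, n = n),
                       noise_series("white", n = n, seed = seed * 300L + k),
                       snr = 1e5), "cep", "chaotic")
  add(logistic_series(3.2, n = n), "indicators", "periodic")
  add(logistic_series(2, n = n), "indicators", "stationary")
  add(lorenz_series(n = n), "cep", "chaotic")
  inst
}

#' Evaluate detectors on the labeled reference suite
#'
#' Runs the appropriate detector on every instance of a [reference_suite()]
#' and reports per-instance correctness: the ordinal verdict
#' ([cep_curve()] + [detect_chaos_cep()]) for stochastic/chaotic classes,
#' the indicator classifier ([classify_series()]) for periodic/stationary
#' ones.
#'
#' @param suite a [reference_suite()].
#' @param d embedding dimension for the ordinal detector. Default 6.
#' @param delays delays for [cep_curve()]. Default `c(1:5, 8, 13, 21, 34)`.
#' @param bounds optional precomputed [complexity_bounds()].
#' @return Data frame with `generator`, `detector`, `expected`, `got`,
#'   `correct`.
#' @export
evaluate_reference_suite <- function(suite, d = 6,
                                     delays = c(1:5, 8, 13, 21, 34),
                                     bounds = NULL) {
  if (is.null(bounds)) bounds <- complexity_bounds(factorial(d))
  rows <- lapply(suite, function(it) {
    got <- if (it$detector == "cep") {
      cv <- cep_curve(it$series$values, d = d, delays = delays,
                      bounds = bounds)
      detect_chaos_cep(cv)$verdict
    } else {
      classify_series(it$series$values)$label
    }
    data.frame(generator = it$series$generator, detector = it$detector,
               expected = it$expected, got = got,
               correct = got == it$expected)
  })
  do.call(rbind, rows)
}
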