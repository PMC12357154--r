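#' Seasonal temperature parameters
#'
#' Parameters of the deterministic sinusoidal annual temperature cycle
#' \deqn{T_{det}(t) = \bar{T} - A_y \cos(2\pi t/\tau_y)}
#' so that the coldest point of the year sits at \eqn{t = 0} and the warmest
#' at mid-year.
#'
#' @param T_bar mean water temperature (degrees C). Default 15.
#' @param A_y amplitude of the annual cycle (degrees C, >= 0). Default 0
#'   (constant temperature).
#' @param tau_y annual period (days, > 0). Default 365.
#' @return An object of class `seasonal_params`.
#' @seealso [seasonal_temperature()], [ou_params()], [stochastic_temperature()]
#' @export
#' @examples
#' sp <- seasonal_params(A_y = 5)
#' seasonal_temperature(c(0, 182.5, 365), sp)
seasonal_params <- function(T_bar = 15, A_y = 0, tau_y = 365) {
  if (!is.numeric(A_y) || length(A_y) != 1L || is.na(A_y) || A_y < 0)
    stop("'A_y' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(tau_y) || length(tau_y) != 1L || is.na(tau_y) || tau_y <= 0)
    stop("'tau_y' must be a single positive number", call. = FALSE)
  structure(list(T_bar = T_bar, A_y = A_y, tau_y = tau_y),
            class = "seasonal_params")
}

#' Ornstein-Uhlenbeck noise parameters
#'
#' Parameters of the mean-reverting Gaussian (red) noise added to the
#' seasonal temperature cycle,
#' \deqn{d\chi_T/dt = -\chi_T/\tau + \xi_T(t), \quad \chi_T(0) = 0,}
#' with \eqn{\xi_T} white Gaussian noise of intensity `D`. For long times the
#' process is stationary with mean 0 and variance \eqn{D\tau/2}
#' (temperature squared); the autocorrelation decays as
#' \eqn{\exp(-\Delta t/\tau)}.
#'
#' `D` is expressed in squared temperature per unit time with all times in
#' days, so that the stationary variance \eqn{D\tau/2} is a squared
#' temperature; the default `D` keeps that variance at 10^-2 for the chosen
#' correlation time.
#'
#' @param tau noise correlation time (days, > 0).
#' @param D noise intensity (degC^2/day, >= 0). Default `2 * 1e-2 / tau`,
#'   which fixes the stationary variance `D * tau / 2` at 10^-2 degC^2.
#' @param seed integer seed for reproducible realizations.
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(tau, D = 2 * 1e-2 / tau, seed = 1L) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("'tau' must be a single positive number", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0)
    stop("'D' must be a single nonnegative number", call. = FALSE)
  structure(list(tau = tau, D = D, seed = as.integer(seed)),
            class = "ou_params")
}

#' Deterministic seasonal temperature
#'
#' @param t time in days (vectorized).
#' @param p a [seasonal_params()] object.
#' @return Temperature in degrees C, same length as `t`; ranges over
#'   `[T_bar - A_y, T_bar + A_y]` with period `tau_y`.
#' @export
seasonal_temperature <- function(t, p = seasonal_params()) {
  stopifnot(inherits(p, "seasonal_params"))
  p$T_bar - p$A_y * cos(2 * pi * t / p$tau_y)
}

#' Simulate an Ornstein-Uhlenbeck noise series
#'
#' Generates a realization of the OU process on a uniform grid using the
#' exact transition density: over a step `dt` the state is multiplied by
#' `exp(-dt/tau)` and receives a Gaussian innovation with variance
#' `(D*tau/2) * (1 - exp(-2*dt/tau))`, so the stationary moments are exact
#' at any step size. The series starts at 0.
#'
#' @param p an [ou_params()] object.
#' @param dt time step (days, > 0).
#' @param n_steps number of steps (>= 1); the returned series has
#'   `n_steps + 1` samples including the initial 0.
#' @param seed optional seed overriding `p$seed`; `NULL` leaves the current
#'   RNG state untouched (used internally for derived streams).
#' @return Numeric vector of length `n_steps + 1`.
#' @export
simulate_ou <- function(p, dt, n_steps, seed = p$seed) {
  stopifnot(inherits(p, "ou_params"))
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  if (p$D == 0) return(numeric(n_steps + 1L))
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-dt / p$tau)
  s_inn <- sqrt((p$D * p$tau / 2) * (1 - a^2))
  z <- stats::rnorm(n_steps, sd = s_inn)
  x <- numeric(n_steps + 1L)
  # exact OU recursion; filter() keeps this O(n) without an R-level loop
  x[-1L] <- as.numeric(stats::filter(z, a, method = "recursive"))
  x
}

#' Total (seasonal + stochastic) temperature series
#'
#' Builds the forcing temperature on a uniform time grid as the sum of the
#' deterministic seasonal cycle and an OU noise realization sampled on the
#' same grid.
#'
#' @param times strictly increasing, uniformly spaced times (days).
#' @param sp a [seasonal_params()] object.
#' @param op an [ou_params()] object, or `NULL` for purely deterministic
#'   forcing.
#' @param seed optional seed overriding `op$seed`.
#' @return A `temperature_series` object: list with `times`, `det`, `noise`
#'   and `total` (`total = det + noise`, `noise[1] == 0`).
#' @export
#' @examples
#' ts <- stochastic_temperature(seq(0, 730, by = 0.5), seasonal_params(A_y = 5),
#'                              ou_params(tau = 30, seed = 42))
#' head(as.data.frame(ts))
stochastic_temperature <- function(times, sp = seasonal_params(), op = NULL,
                                   seed = if (is.null(op)) NULL else op$seed) {
  if (length(times) < 2L) stop("'times' must have at least 2 samples", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (max(dts) - min(dts) > 1e-8 * mean(dts))
    stop("'times' must be uniformly spaced", call. = FALSE)
  det <- seasonal_temperature(times, sp)
  if (is.null(op) || op$D == 0) {
    noise <- numeric(length(times))
  } else {
    noise <- simulate_ou(op, dt = mean(dts), n_steps = length(times) - 1L,
                         seed = seed)
  }
  structure(list(times = times, det = det, noise = noise,
                 total = det + noise, seasonal = sp, ou = op),
            class = "temperature_series")
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(time_days = x$times, T_det = x$det, T_noise = x$noise,
             T_total = x$total)
}

#' @export
print.temperature_series <- function(x, ...) {
  cat("Temperature forcing series\n")
  cat(sprintf("  %d samples over %.1f days (dt = %.4g d)\n", length(x$times),
              diff(range(x$times)), x$times[2] - x$times[1]))
  cat(sprintf("  seasonal: T_bar = %g, A_y = %g, tau_y = %g d\n",
              x$seasonal$T_bar, x$seasonal$A_y, x$seasonal$tau_y))
  if (!is.null(x$ou))
    cat(sprintf("  OU noise: tau = %g d, D = %g (stationary var %g)\n",
                x$ou$tau, x$ou$D, x$ou$D * x$ou$tau / 2))
  invisible(x)
}

#' Write a temperature series as CSV
#'
#' @param x a `temperature_series`.
#' @param file path to write; columns `time_days, T_det, T_noise, T_total`.
#' @return `file`, invisibly.
#' @export
write_temperature_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}
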