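#' Maximal Lyapunov exponent of an iterated map (Wolf algorithm)
#'
#' Companion-trajectory variant: a second orbit at tiny separation is
#' iterated through the same map and renormalized back to the initial
#' separation at every step; the exponent is the mean log stretching per
#' iteration.
#'
#' @param f one-dimensional map, a function of `x`.
#' @param x0 initial condition.
#' @param n_iter iterations used for the average. Default 2e5.
#' @param burn_in discarded transient iterations. Default 1000.
#' @param d0 companion separation. Default 1e-9.
#' @return `lambda` per iteration.
#' @export
#' @examples
#' lyapunov_wolf_map(function(x) 4 * x * (1 - x), 0.2)  # ~ log(2)
lyapunov_wolf_map <- function(f, x0, n_iter = 2e5, burn_in = 1000,
                              d0 = 1e-9) {
  x <- x0
  for (k in seq_len(burn_in)) x <- f(x)
  y <- x + d0
  s <- 0
  for (k in seq_len(n_iter)) {
    x <- f(x)
    y <- f(y)
    d1 <- abs(y - x)
    if (d1 == 0) d1 <- .Machine$double.xmin
    s <- s + log(d1 / d0)
    y <- x + sign(y - x) * d0
  }
  s / n_iter
}

# single classical RK4 step for an autonomous field f(x)
rk4_step_r <- function(f, x, dt) {
  k1 <- f(x)
  k2 <- f(x + dt / 2 * k1)
  k3 <- f(x + dt / 2 * k2)
  k4 <- f(x + dt * k3)
  x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Maximal Lyapunov exponent of a flow (Wolf algorithm)
#'
#' Companion-trajectory variant for a known autonomous vector field,
#' integrated with fixed-step RK4; the companion is renormalized every
#' `renorm_every` steps.
#'
#' @param f vector field, a function of the state vector.
#' @param x0 initial state.
#' @param dt integration step (in the flow's time unit).
#' @param n_steps measurement steps. Default 1e5.
#' @param burn_in discarded transient steps. Default 5000.
#' @param d0 relative companion separation. Default 1e-7.
#' @param renorm_every steps between renormalizations. Default 10.
#' @return `lambda` per unit time.
#' @export
lyapunov_wolf_flow <- function(f, x0, dt, n_steps = 1e5, burn_in = 5000,
                               d0 = 1e-7, renorm_every = 10) {
  x <- x0
  for (k in seq_len(burn_in)) x <- rk4_step_r(f, x, dt)
  dsep <- d0 * max(sqrt(sum(x^2)), 1)
  y <- x + dsep / sqrt(length(x))
  s <- 0
  n_ren <- 0
  for (k in seq_len(n_steps)) {
    x <- rk4_step_r(f, x, dt)
    y <- rk4_step_r(f, y, dt)
    if (k %% renorm_every == 0) {
      d1 <- sqrt(sum((y - x)^2))
      if (d1 == 0) d1 <- .Machine$double.xmin
      s <- s + log(d1 / dsep)
      y <- x + (y - x) * dsep / d1
      n_ren <- n_ren + 1
    }
  }
  s / (n_ren * renorm_every * dt)
}

#' Maximal Lyapunov exponent of a scalar time series (Wolf algorithm)
#'
#' Classical embedding variant for externally supplied series: the series
#' is delay-embedded, a nearest neighbor of the fiducial point is tracked
#' for `evolve` steps, the log divergence is accumulated, and a new
#' neighbor is picked (closest point within the search radius, excluding
#' temporal neighbors). Intended for clean, densely sampled deterministic
#' series; for noisy data prefer the ordinal-pattern machinery
#' ([detect_chaos_cep()]).
#'
#' @param series numeric vector.
#' @param emb_dim embedding dimension. Default 6.
#' @param delay embedding delay in samples; by default the first zero
#'   crossing of the autocorrelation (capped at a tenth of the series).
#' @param dt sampling interval in the series' time unit. Default 1.
#' @param evolve steps between renormalizations. Default `max(5, delay)`.
#' @param theiler temporal exclusion window (samples). Default `10 * delay`.
#' @return `lambda` per unit time.
#' @export
lyapunov_wolf_series <- function(series, emb_dim = 6, delay = NULL, dt = 1,
                                 evolve = NULL, theiler = NULL) {
  if (is.null(delay)) {
    ac <- stats::acf(series, lag.max = min(length(series) %/% 10, 1000),
                     plot = FALSE)$acf[-1]
    z <- which(ac <= 0)
    delay <- if (length(z)) max(1L, z[1]) else max(1L, length(ac) %/% 4)
  }
  if (is.null(evolve)) evolve <- max(5L, delay)
  if (is.null(theiler)) theiler <- 10L * delay
  n <- length(series)
  m <- n - (emb_dim - 1L) * delay
  if (m < 50L) stop("series too short to embed", call. = FALSE)
  emb <- vapply(0:(emb_dim - 1L), function(j)
    series[seq_len(m) + j * delay], numeric(m))
  i_fid <- 1L
  # initial neighbor: nearest outside the Theiler window
  nn_of <- function(i, exclude_radius) {
    d2 <- rowSums((emb - matrix(emb[i, ], m, emb_dim, byrow = TRUE))^2)
    d2[pmax(1, i - exclude_radius):pmin(m, i + exclude_radius)] <- Inf
    d2[m] <- Inf  # must be evolvable
    which.min(d2)
  }
  j <- nn_of(i_fid, theiler)
  s <- 0
  t_total <- 0
  while (i_fid + evolve < m && j + evolve < m) {
    d_start <- sqrt(sum((emb[i_fid, ] - emb[j, ])^2))
    if (d_start == 0) d_start <- .Machine$double.xmin
    i2 <- i_fid + evolve
    j2 <- j + evolve
    d_end <- sqrt(sum((emb[i2, ] - emb[j2, ])^2))
    if (d_end == 0) d_end <- .Machine$double.xmin
    s <- s + log(d_end / d_start)
    t_total <- t_total + evolve * dt
    i_fid <- i2
    j <- nn_of(i_fid, theiler)
    if (j >= m - evolve) break
  }
  if (t_total == 0) stop("could not evolve any neighbor pair", call. = FALSE)
  s / t_total
}

#' Maximal Lyapunov exponent of a food-web configuration
#'
#' Model-based Wolf estimate through the known reduced food-web equations:
#' a companion trajectory at small separation (projected onto the
#' constant-mass subspace) is advanced with the same temperature forcing
#' and renormalized at ~1-day intervals.
#'
#' @param config a [foodweb_config()].
#' @param forcing [seasonal_params()] or a `temperature_series` covering
#'   `transient_years + measure_years`.
#' @param transient_years discarded transient. Default 20.
#' @param measure_years measurement span. Default 60.
#' @param steps_per_year integration grid. Default 5000.
#' @param d0 relative separation. Default 1e-7.
#' @return `lambda` in day^-1.
#' @export
foodweb_lyapunov <- function(config, forcing = seasonal_params(),
                             transient_years = 20, measure_years = 60,
                             steps_per_year = 5000, d0 = 1e-7) {
  dt <- 365 / steps_per_year
  n_steps <- round((transient_years + measure_years) * steps_per_year)
  if (inherits(forcing, "seasonal_params")) {
    temperature <- seasonal_temperature(seq(0, by = dt,
                                            length.out = n_steps + 1), forcing)
  } else if (inherits(forcing, "temperature_series")) {
    if (length(forcing$total) < n_steps + 1)
      stop("forcing series shorter than transient + measurement", call. = FALSE)
    temperature <- forcing$total[seq_len(n_steps + 1)]
  } else stop("invalid forcing", call. = FALSE)
  res <- .foodweb_lyapunov_cpp(foodweb_initial_state(config),
                               foodweb_par_vector(config), temperature, dt,
                               transient_steps = round(transient_years *
                                                         steps_per_year),
                               d0 = d0)
  if (res$status == 1)
    stop("integration failure during Lyapunov estimation", call. = FALSE)
  if (res$status == 2) {
    warning("degenerate orbit (zero state); returning -Inf")
    return(-Inf)
  }
  res$lambda
}
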