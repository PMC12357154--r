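#' Q10 temperature regulation factor
#'
#' Multiplicative change of a metabolic rate with temperature,
#' \deqn{f_T(T) = Q_{10}^{(T - T_{ref})/10},}
#' equal to 1 at the reference temperature and multiplied by `Q10` for every
#' 10 degrees C of warming. All organisms use `Q10 = 2` except heterotrophic
#' bacteria, which use `Q10 = 2.95`.
#'
#' @param T temperature (degrees C, vectorized).
#' @param Q10 dimensionless sensitivity (> 0).
#' @param T_ref reference temperature (degrees C). Default 10.
#' @return Dimensionless multiplier, same length as `T`.
#' @export
#' @examples
#' q10_factor(20, Q10 = 2.95)  # bacterial rate doubling-plus at +10 degC
q10_factor <- function(T, Q10, T_ref = 10) {
  if (!is.numeric(Q10) || length(Q10) != 1L || is.na(Q10) || Q10 <= 0)
    stop("'Q10' must be a single positive number", call. = FALSE)
  Q10^((T - T_ref) / 10)
}

# names and order of the state pools; carbon in mgC m^-3, N in mmolP m^-3
foodweb_pools <- function() c("P1", "P2", "Z1", "Z2", "B", "D", "N")

#' Reduced plankton food-web configuration
#'
#' Defines a 7-pool, single-currency (carbon, with a fixed phosphorus quota)
#' plankton food web: two producers (`P1` fast/high half-saturation, `P2`
#' slow/oligotrophic), microzooplankton `Z1` (grazing both producers and
#' bacteria), mesozooplankton `Z2` (grazing `Z1` and the producers),
#' heterotrophic bacteria `B` remineralizing a detritus/dissolved organic
#' pool `D`, and one dissolved nutrient pool `N` (phosphate). Every flux is
#' a transfer between pools, so the phosphorus-equivalent mass
#' `q * (sum of carbon pools) + N` is conserved exactly by the vector field.
#'
#' Growth and grazing rates are modulated by the [q10_factor()] of the
#' forcing temperature (`Q10 = 2`, bacteria `Q10_b = 2.95`, `T_ref = 10`
#' degrees C), nutrient limitation is Monod, grazing is Holling type II with
#' preference weights, and basal respiration/mortality are linear. The
#' consumer uptake is split into growth `eta_z * (1 - beta_z)`, excretion
#' `eta_z * beta_z` (remineralized to `N`) and unassimilated egestion
#' `1 - eta_z` (to `D`).
#'
#' @param PO4_0 initial dissolved nutrient concentration (mmol P m^-3).
#' @param beta_z consumer excreted fraction of uptake, in `[0, 1]`.
#' @param eta_z consumer assimilation efficiency, in `(0, 1]`.
#' @param f_I constant light-limitation factor in `[0, 1]`.
#' @param r_max producer maximum growth rates (1/day), length 2.
#' @param k_N producer nutrient half-saturation constants (mmol P m^-3).
#' @param s_p,x_p,m_p producer respiration, excretion, mortality (1/day).
#' @param g_max consumer maximum uptake rates (1/day), `c(Z1, Z2)`.
#' @param K_F consumer food half-saturation constants (mgC m^-3).
#' @param pref_z1 Z1 preferences for `c(P1, P2, B)`.
#' @param pref_z2 Z2 preferences for `c(P1, P2, Z1)`.
#' @param s_z,m_z consumer respiration and mortality (1/day), `c(Z1, Z2)`.
#' @param u_B,k_D,e_B,s_B bacterial maximum uptake (1/day), half-saturation
#'   on `D` (mgC m^-3), growth efficiency and respiration (1/day).
#' @param Q10,Q10_b,T_ref temperature regulation parameters.
#' @param q phosphorus quota (mmol P per mgC); default Redfield,
#'   `1 / (12.011 * 106)`.
#' @param init_biomass named initial carbon concentrations (mgC m^-3) for
#'   `P1 P2 Z1 Z2 B D`.
#' @return An object of class `foodweb_config`.
#' @seealso [preset_config()] for the calibrated ES/EP/EC regimes,
#'   [integrate_foodweb()] to simulate.
#' @export
foodweb_config <- function(PO4_0 = 0.055, beta_z = 0.60, eta_z = 0.50,
                           f_I = 1.0,
                           r_max = c(2.37, 1.23), k_N = c(0.064, 0.0174),
                           s_p = c(0.05, 0.05), x_p = c(0.05, 0.05),
                           m_p = c(0.05, 0.05),
                           g_max = c(1.655, 0.893), K_F = c(13.58, 11.30),
                           pref_z1 = c(P1 = 0.475, P2 = 0.474, B = 0.431),
                           pref_z2 = c(P1 = 0.553, P2 = 0, Z1 = 1.0),
                           s_z = c(0.02, 0.015), m_z = c(0.0613, 0.0761),
                           u_B = 1.843, k_D = 43.6, e_B = 0.3, s_B = 0.05,
                           Q10 = 2.0, Q10_b = 2.95, T_ref = 10,
                           q = 1 / (12.011 * 106),
                           init_biomass = c(P1 = 5, P2 = 5, Z1 = 2, Z2 = 2,
                                            B = 2, D = 10)) {
  stopifnot(length(r_max) == 2, length(k_N) == 2, length(g_max) == 2,
            length(K_F) == 2, length(pref_z1) == 3, length(pref_z2) == 3,
            length(init_biomass) == 6)
  if (eta_z <= 0 || eta_z > 1) stop("'eta_z' must be in (0, 1]", call. = FALSE)
  if (beta_z < 0 || beta_z > 1) stop("'beta_z' must be in [0, 1]", call. = FALSE)
  if (f_I < 0 || f_I > 1) stop("'f_I' must be in [0, 1]", call. = FALSE)
  rates <- c(r_max, s_p, x_p, m_p, g_max, s_z, m_z, u_B, s_B, k_N, K_F, k_D,
             pref_z1, pref_z2)
  if (any(rates < 0)) stop("rates and half-saturations must be >= 0", call. = FALSE)
  if (Q10 <= 0 || Q10_b <= 0) stop("Q10 values must be positive", call. = FALSE)
  structure(list(PO4_0 = PO4_0, beta_z = beta_z, eta_z = eta_z, f_I = f_I,
                 r_max = r_max, k_N = k_N, s_p = s_p, x_p = x_p, m_p = m_p,
                 g_max = g_max, K_F = K_F,
                 pref_z1 = pref_z1, pref_z2 = pref_z2,
                 s_z = s_z, m_z = m_z,
                 u_B = u_B, k_D = k_D, e_B = e_B, s_B = s_B,
                 Q10 = Q10, Q10_b = Q10_b, T_ref = T_ref, q = q,
                 init_biomass = init_biomass),
            class = "foodweb_config")
}

#' @export
print.foodweb_config <- function(x, ...) {
  cat("Reduced plankton food-web configuration (7 pools)\n")
  cat(sprintf("  PO4_0 = %g mmolP m-3, beta_z = %g, eta_z = %g, f_I = %g\n",
              x$PO4_0, x$beta_z, x$eta_z, x$f_I))
  cat(sprintf("  Q10 = %g (bacteria %g), T_ref = %g degC\n",
              x$Q10, x$Q10_b, x$T_ref))
  invisible(x)
}

# flat parameter vector consumed by the compiled derivative
foodweb_par_vector <- function(config) {
  with(config, c(q, f_I, T_ref, Q10, Q10_b,
                 r_max, k_N, s_p, x_p, m_p,
                 g_max[1], K_F[1], pref_z1,
                 g_max[2], K_F[2], pref_z2,
                 eta_z, beta_z, s_z, m_z,
                 u_B, k_D, e_B, s_B))
}

# initial state from config
foodweb_initial_state <- function(config) {
  x <- c(config$init_biomass, N = config$PO4_0)
  names(x) <- foodweb_pools()
  x
}

#' Gross primary production flux
#'
#' Entry point of carbon into the web: the product of the maximum growth
#' rate, the temperature factor, the light factor, Monod nutrient limitation
#' and the producer biomass,
#' `r_max * f_T(T) * f_I * N/(N + k_N) * P`.
#'
#' @param P producer biomass (mgC m^-3).
#' @param N dissolved nutrient (mmol P m^-3).
#' @param T temperature (degrees C).
#' @param config a [foodweb_config()].
#' @param producer which producer (1 or 2) supplies `r_max` and `k_N`.
#' @return Flux in mgC m^-3 day^-1.
#' @export
gross_primary_production <- function(P, N, T, config = foodweb_config(),
                                     producer = 1L) {
  stopifnot(P >= 0, producer %in% 1:2)
  config$r_max[producer] * q10_factor(T, config$Q10, config$T_ref) *
    config$f_I * (N / (N + config$k_N[producer])) * P
}

#' Food-web time derivatives
#'
#' Evaluates the vector field of the reduced food web at one state and
#' temperature. The producer balance is gross primary production minus
#' respiration, excretion, mortality and predation; consumers gain
#' `eta_z * (1 - beta_z)` of their Holling-II uptake; bacteria remineralize
#' the detritus pool back to the nutrient. The phosphorus-weighted sum of
#' the derivatives is zero by construction.
#'
#' @param state named state vector (`P1 P2 Z1 Z2 B D N`).
#' @param T temperature (degrees C).
#' @param config a [foodweb_config()].
#' @param use_compiled use the compiled derivative (default) or the plain-R
#'   reference implementation.
#' @return Named derivative vector (per day).
#' @export
foodweb_derivatives <- function(state, T, config = foodweb_config(),
                                use_compiled = TRUE) {
  stopifnot(length(state) == 7L)
  if (use_compiled) {
    d <- .foodweb_derivatives_cpp(as.numeric(state), T,
                                  foodweb_par_vector(config))
    names(d) <- foodweb_pools()
    return(d)
  }
  cf <- config
  fTp <- q10_factor(T, cf$Q10, cf$T_ref)
  fTb <- q10_factor(T, cf$Q10_b, cf$T_ref)
  P <- state[1:2]; Z <- state[3:4]; B <- state[5]; D <- state[6]; N <- state[7]
  gpp <- cf$r_max * fTp * cf$f_I * (N / (N + cf$k_N)) * P
  rsp <- cf$s_p * fTp * P
  exc <- cf$x_p * fTp * P
  mor <- cf$m_p * P
  graze <- function(prey, pref, g, K, Zc) {
    a <- pref * prey
    sq <- sum(a * prey)
    Feff <- if (sum(a) > 0) sq / sum(a) else 0
    G <- g * fTp * Feff / (K + Feff) * Zc
    list(total = G, per_prey = if (sq > 0) G * a * prey / sq else numeric(3))
  }
  gz1 <- graze(c(P, B), cf$pref_z1, cf$g_max[1], cf$K_F[1], Z[1])
  gz2 <- graze(c(P, Z[1]), cf$pref_z2, cf$g_max[2], cf$K_F[2], Z[2])
  G1 <- gz1$total; G1k <- gz1$per_prey
  G2 <- gz2$total; G2k <- gz2$per_prey
  rz <- cf$s_z * fTp * Z
  mz <- cf$m_z * Z
  upt <- cf$u_B * fTb * (D / (D + cf$k_D)) * B
  rB <- cf$s_B * fTb * B
  dx <- c(
    gpp[1] - rsp[1] - exc[1] - mor[1] - G1k[1] - G2k[1],
    gpp[2] - rsp[2] - exc[2] - mor[2] - G1k[2] - G2k[2],
    cf$eta_z * (1 - cf$beta_z) * G1 - rz[1] - mz[1] - G2k[3],
    cf$eta_z * (1 - cf$beta_z) * G2 - rz[2] - mz[2],
    cf$e_B * upt - rB - G1k[3],
    sum(exc) + sum(mor) + (1 - cf$eta_z) * (G1 + G2) + sum(mz) - upt,
    cf$q * (-sum(gpp) + sum(rsp) + cf$eta_z * cf$beta_z * (G1 + G2) +
              sum(rz) + (1 - cf$e_B) * upt + rB)
  )
  names(dx) <- foodweb_pools()
  dx
}

#' Simulate the food web under temperature forcing
#'
#' Fixed-step 4th-order Runge-Kutta integration on the standard grid of
#' `steps_per_year` steps per 365-day year (the default 5000 corresponds to
#' a 6307.2 s step). Deterministic forcing is evaluated analytically on the
#' grid; stochastic forcing must be supplied as a `temperature_series`
#' sampled on the same grid. Concentrations are clipped at zero only for
#' undershoots smaller than `clip_tol`; larger negative or non-finite
#' values abort with an integration-failure error.
#'
#' @param config a [foodweb_config()].
#' @param forcing a [seasonal_params()] object or a `temperature_series`
#'   from [stochastic_temperature()].
#' @param years simulated years (>= 1). Default 20.
#' @param steps_per_year integration steps per year. Default 5000.
#' @param clip_tol absolute tolerance for clipping integrator undershoots.
#' @return A `foodweb_trajectory`: list with `times` (days), `state`
#'   (matrix, samples x pools), `pools`, `forcing`, `config`, `dt`.
#' @export
#' @examples
#' traj <- integrate_foodweb(preset_config("ES"), seasonal_params(A_y = 0),
#'                           years = 2)
#' tail(traj$state[, "P1"], 3)
integrate_foodweb <- function(config, forcing = seasonal_params(),
                              years = 20, steps_per_year = 5000,
                              clip_tol = 1e-8) {
  stopifnot(inherits(config, "foodweb_config"), years >= 1)
  dt <- 365 / steps_per_year
  n_steps <- round(years * steps_per_year)
  if (inherits(forcing, "seasonal_params")) {
    times <- seq(0, by = dt, length.out = n_steps + 1)
    temperature <- seasonal_temperature(times, forcing)
    frec <- list(kind = "deterministic", seasonal = forcing)
  } else if (inherits(forcing, "temperature_series")) {
    times <- forcing$times
    if (length(times) != n_steps + 1 ||
        abs(times[2] - times[1] - dt) > 1e-9 * dt)
      stop("forcing series grid does not match the integration grid",
           call. = FALSE)
    temperature <- forcing$total
    frec <- list(kind = "stochastic", seasonal = forcing$seasonal,
                 ou = forcing$ou)
  } else stop("'forcing' must be seasonal_params or temperature_series",
              call. = FALSE)
  res <- .foodweb_integrate_cpp(foodweb_initial_state(config),
                                foodweb_par_vector(config), temperature, dt,
                                clip_tol)
  if (res$status != 0)
    stop(sprintf("integration failure at step %d (t = %.2f d): %s",
                 res$fail_step, res$fail_step * dt,
                 "negative or non-finite concentration"), call. = FALSE)
  state <- res$state
  colnames(state) <- foodweb_pools()
  structure(list(times = times, state = state, pools = foodweb_pools(),
                 temperature = temperature, forcing = frec, config = config,
                 dt = dt, steps_per_year = steps_per_year, years = years),
            class = "foodweb_trajectory")
}

#' @export
print.foodweb_trajectory <- function(x, ...) {
  cat(sprintf("Food-web trajectory: %g years, %d steps/year (dt = %.4g d)\n",
              x$years, x$steps_per_year, x$dt))
  cat(sprintf("  forcing: %s\n", x$forcing$kind))
  fin <- x$state[nrow(x$state), ]
  cat("  final state:\n")
  print(round(fin, 5))
  invisible(x)
}

#' @export
as.data.frame.foodweb_trajectory <- function(x, ...) {
  data.frame(time_days = x$times, x$state, check.names = FALSE)
}

#' Write a trajectory as CSV
#' @param x a `foodweb_trajectory`.
#' @param file output path; columns `time_days` then one per pool.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Phosphorus-equivalent total mass along a trajectory
#'
#' @param x a `foodweb_trajectory` (or a state vector/matrix).
#' @param config configuration supplying the quota `q` (taken from the
#'   trajectory when available).
#' @return Vector of total mass (mmol P m^-3) per sample.
#' @export
total_mass <- function(x, config = NULL) {
  if (inherits(x, "foodweb_trajectory")) {
    config <- x$config
    x <- x$state
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  config$q * rowSums(x[, 1:6, drop = FALSE]) + x[, 7]
}

#' Extract the analysis window of a trajectory
#'
#' Returns per-pool series over the last `window_years` years, the window
#' used by all indicators and diagrams to discard transients.
#'
#' @param x a `foodweb_trajectory`.
#' @param window_years length of the terminal window (years). Default 10.
#' @return List with `times` and `state` restricted to the window.
#' @export
trajectory_window <- function(x, window_years = 10) {
  t_end <- x$times[length(x$times)]
  keep <- x$times > t_end - window_years * 365 + 1e-9
  if (!any(keep)) stop("window longer than trajectory", call. = FALSE)
  list(times = x$times[keep], state = x$state[keep, , drop = FALSE])
}
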