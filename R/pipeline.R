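#' Experiment configuration
#'
#' Bundles everything needed to rerun a forcing experiment: preset,
#' amplitude grid, noise time scales, stationary noise variance (fixing
#' `D = 2 * variance / tau` per time scale), ensemble size, simulation
#' grid and master seed. Writable to / readable from YAML.
#'
#' @param preset `"ES"`, `"EP"` or `"EC"`.
#' @param amplitudes seasonal amplitude grid (degrees C). Default `0:15`.
#' @param taus noise correlation times (days). Default
#'   `c(10, 30, 90, 180, 365)`.
#' @param noise_variance stationary OU variance (degC^2). Default 1e-2.
#' @param realizations ensemble size. Default 100.
#' @param years,steps_per_year simulation grid. Defaults 20, 5000.
#' @param master_seed master seed for realization streams. Default 1.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(preset = "ES", amplitudes = 0:15,
                              taus = c(10, 30, 90, 180, 365),
                              noise_variance = 1e-2, realizations = 100,
                              years = 20, steps_per_year = 5000,
                              master_seed = 1L) {
  stopifnot(preset %in% c("ES", "EP", "EC"), noise_variance >= 0,
            realizations >= 1, years >= 1)
  structure(list(preset = preset, amplitudes = amplitudes, taus = taus,
                 noise_variance = noise_variance,
                 realizations = as.integer(realizations), years = years,
                 steps_per_year = as.integer(steps_per_year),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param x an `experiment_config`.
#' @param file path of the YAML file.
#' @export
write_experiment_config <- function(x, file) {
  stopifnot(inherits(x, "experiment_config"))
  yaml::write_yaml(c(list(schema = "planktonchaos/experiment/1"),
                     unclass(x)), file)
  invisible(file)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!identical(y$schema, "planktonchaos/experiment/1"))
    stop("not a planktonchaos experiment config", call. = FALSE)
  y$schema <- NULL
  do.call(experiment_config, y)
}

# deterministic per-realization seed stream below 2^31
realization_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) * 10007 + 7919 * k) %% 2147483647L)
}

#' Deterministic amplitude sweep
#'
#' Runs one 20-year simulation per seasonal amplitude for a preset,
#' classifies each trajectory and builds the bifurcation diagram.
#'
#' @param preset preset name or a [foodweb_config()].
#' @param amplitudes amplitude grid (degrees C). Default `0:15`.
#' @param years,steps_per_year simulation grid.
#' @param lambda_measure_years Lyapunov measurement span (years). Default 60.
#' @return List with `classifications` (data frame: amplitude, label, cv,
#'   lambda, min_biomass) and `diagram` (a `bifurcation_diagram`).
#' @export
run_deterministic_sweep <- function(preset, amplitudes = 0:15, years = 20,
                                    steps_per_year = 5000,
                                    lambda_measure_years = 60) {
  config <- if (inherits(preset, "foodweb_config")) preset
  else preset_config(preset)
  diagram <- build_bifurcation(config, amplitudes, years = years,
                               steps_per_year = steps_per_year,
                               lambda_measure_years = lambda_measure_years)
  rows <- lapply(amplitudes, function(A) {
    tr <- tryCatch(integrate_foodweb(config, seasonal_params(A_y = A),
                                     years = years,
                                     steps_per_year = steps_per_year),
                   error = function(e) NULL)
    if (is.null(tr))
      return(data.frame(amplitude = A, label = "failed", cv = NA,
                        lambda = NA, min_biomass = NA))
    cl <- classify_trajectory(tr,
                              lambda_measure_years = lambda_measure_years)
    data.frame(amplitude = A, label = cl$label, cv = cl$cv,
               lambda = cl$lambda_max, min_biomass = cl$min_biomass)
  })
  list(classifications = do.call(rbind, rows), diagram = diagram)
}

#' Stochastic forcing ensemble with ordinal analysis
#'
#' Runs `realizations` independent simulations under seasonal forcing plus
#' OU temperature noise of correlation time `tau`, analyzes the
#' (deseasonalized, daily-thinned) biomass of the focal pool on the
#' multiscale complexity-entropy plane, and aggregates the per-realization
#' verdicts.
#'
#' @param preset preset name or [foodweb_config()].
#' @param tau noise correlation time (days).
#' @param realizations ensemble size. Default 100.
#' @param A_y seasonal amplitude (degrees C). Default 5.
#' @param noise_variance stationary OU variance (degC^2); sets
#'   `D = 2 * noise_variance / tau`. Default 1e-2.
#' @param years,steps_per_year simulation grid. Defaults 20, 5000.
#' @param pool analyzed pool. Default `"P1"` (diatom-like producer).
#' @param d embedding dimension. Default 6.
#' @param delays embedding delays in thinned samples; default a geometric
#'   grid from 1 sample to one year.
#' @param thin thinning factor applied to the output grid before ordinal
#'   analysis (must divide `steps_per_year`). Default
#'   `steps_per_year / 500`, i.e. ~0.7-day sampling.
#' @param master_seed seed of the realization stream. Default 1.
#' @param bounds optional precomputed [complexity_bounds()].
#' @return An `ensemble_summary`: list with `verdicts` (table),
#'   `per_realization` (data frame), `mean_curve` (average HS/CJS per
#'   delay), `failed` (realization ids), and provenance fields.
#' @export
run_stochastic_ensemble <- function(preset, tau, realizations = 100,
                                    A_y = 5, noise_variance = 1e-2,
                                    years = 20, steps_per_year = 5000,
                                    pool = "P1", d = 6, delays = NULL,
                                    thin = NULL, master_seed = 1L,
                                    bounds = NULL) {
  config <- if (inherits(preset, "foodweb_config")) preset
  else preset_config(preset)
  if (is.null(thin)) thin <- max(1L, steps_per_year %/% 500L)
  if (steps_per_year %% thin != 0)
    stop("'thin' must divide steps_per_year", call. = FALSE)
  spy_thin <- steps_per_year %/% thin
  if (is.null(delays))
    delays <- unique(round(exp(seq(0, log(spy_thin), length.out = 15))))
  if (is.null(bounds)) bounds <- complexity_bounds(factorial(d))
  dt <- 365 / steps_per_year
  n_steps <- years * steps_per_year
  times <- seq(0, by = dt, length.out = n_steps + 1)
  sp <- seasonal_params(A_y = A_y)
  rows <- list()
  curves <- list()
  failed <- integer(0)
  seeds <- vapply(seq_len(realizations), function(k)
    realization_seed(master_seed, k), integer(1))
  for (k in seq_len(realizations)) {
    op <- ou_params(tau = tau, D = 2 * noise_variance / tau,
                    seed = seeds[k])
    forcing <- stochastic_temperature(times, sp, op)
    tr <- tryCatch(integrate_foodweb(config, forcing, years = years,
                                     steps_per_year = steps_per_year),
                   error = function(e) NULL)
    if (is.null(tr)) {
      failed <- c(failed, k)
      next
    }
    idx <- seq(1L, n_steps + 1L, by = thin)
    ser <- tr$state[idx, pool]
    tt <- tr$times[idx]
    res <- deseasonalize(ser, tt, period = 365)
    cv <- cep_curve(res, d = d, delays = delays, bounds = bounds)
    vd <- detect_chaos_cep(cv)
    rows[[length(rows) + 1L]] <- data.frame(
      realization = k, seed = seeds[k], verdict = vd$verdict,
      n_chaotic_delays = if (vd$verdict == "chaotic")
        length(vd$supporting_delays) else 0L)
    curves[[length(curves) + 1L]] <- cv[, c("eps", "HS", "CJS")]
  }
  per <- do.call(rbind, rows)
  mean_curve <- NULL
  if (length(curves)) {
    allc <- do.call(rbind, curves)
    mean_curve <- stats::aggregate(allc[c("HS", "CJS")],
                                   by = list(eps = allc$eps), FUN = mean)
  }
  structure(list(verdicts = table(per$verdict), per_realization = per,
                 mean_curve = mean_curve, failed = failed,
                 preset = if (is.character(preset)) preset else "custom",
                 tau = tau, A_y = A_y, noise_variance = noise_variance,
                 master_seed = master_seed, seeds = seeds,
                 realizations = realizations, pool = pool),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: preset %s, tau = %g d, A_y = %g, %d realizations\n",
              x$preset, x$tau, x$A_y, x$realizations))
  print(x$verdicts)
  if (length(x$failed)) cat("  failed realizations:",
                            paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Regime summary across forcing conditions
#'
#' Tabulates the Fig.-style comparison of dynamical regimes for the three
#' presets across forcing conditions: unforced, seasonal forcing only, and
#' seasonal plus stochastic forcing (ordinal verdicts aggregated over
#' realizations; a preset-tau condition counts as chaotic when any
#' realization is).
#'
#' @param unforced named list (by preset) of `classification` objects.
#' @param forced named list (by preset) of `classification` objects under
#'   seasonal forcing.
#' @param stochastic list of `ensemble_summary` objects.
#' @return Data frame with one row per preset and condition, and the label
#'   (or chaos fraction for the stochastic condition).
#' @export
summarize_conditions <- function(unforced = list(), forced = list(),
                                 stochastic = list()) {
  rows <- list()
  for (p in names(unforced))
    rows[[length(rows) + 1L]] <- data.frame(
      preset = p, condition = "unforced", label = unforced[[p]]$label,
      chaos_fraction = as.numeric(unforced[[p]]$label == "chaotic"))
  for (p in names(forced))
    rows[[length(rows) + 1L]] <- data.frame(
      preset = p, condition = "seasonal", label = forced[[p]]$label,
      chaos_fraction = as.numeric(forced[[p]]$label == "chaotic"))
  for (s in stochastic) {
    n <- sum(s$verdicts)
    ch <- if ("chaotic" %in% names(s$verdicts))
      as.numeric(s$verdicts["chaotic"]) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      preset = s$preset, condition = sprintf("seasonal+noise tau=%g", s$tau),
      label = if (ch > 0) "chaotic" else names(which.max(s$verdicts)),
      chaos_fraction = ch / n)
  }
  do.call(rbind, rows)
}
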