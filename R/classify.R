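#' Coefficient of variation
#'
#' Ratio of the population standard deviation to the mean over the analysis
#' window, the stationarity indicator: solutions with `CV < 1e-3` are
#' treated as stationary.
#'
#' @param series numeric vector of length >= 2 with nonzero mean.
#' @return `sigma / mu` (dimensionless, scale invariant).
#' @export
#' @examples
#' coefficient_of_variation(c(1, 1, 1, 3))  # 0.5774
coefficient_of_variation <- function(series) {
  if (length(series) < 2L) stop("need at least 2 samples", call. = FALSE)
  mu <- mean(series)
  if (mu == 0) stop("undefined CV: series mean is zero", call. = FALSE)
  sqrt(mean((series - mu)^2)) / mu
}

#' Spectral character of a series
#'
#' Summarizes the detrended periodogram as one of three verdicts:
#' `"monotonic"` for a drifting (monotone) series, `"discrete-peaks"` when
#' a small harmonically related set of peaks captures almost all of the
#' detrended variance (periodic dynamics), `"broadband"` otherwise
#' (aperiodic/chaotic/noisy dynamics).
#'
#' @param series numeric vector on a uniform grid.
#' @param peak_energy fraction of spectral power the peak set must capture
#'   for a periodic verdict. Default 0.99.
#' @param max_peaks maximum number of peak clusters for a periodic verdict.
#'   Default 8.
#' @return Character scalar.
#' @export
spectral_verdict <- function(series, peak_energy = 0.99, max_peaks = 8) {
  n <- length(series)
  if (n < 16L) stop("series too short for a spectral verdict", call. = FALSE)
  dif <- diff(series)
  if (all(dif >= 0) || all(dif <= 0)) return("monotonic")
  # full cosine-bell taper keeps tone leakage inside a few bins
  sp <- stats::spec.pgram(stats::ts(series), taper = 0.5, detrend = TRUE,
                          fast = TRUE, plot = FALSE)
  pw <- sp$spec
  total <- sum(pw)
  if (total == 0) return("monotonic")
  # greedy peak clusters: strongest bins with +-4 bin sidebands
  ord <- order(pw, decreasing = TRUE)
  taken <- logical(length(pw))
  centers <- integer(0)
  energy <- 0
  for (i in ord) {
    if (taken[i]) next
    win <- max(1L, i - 4L):min(length(pw), i + 4L)
    centers <- c(centers, i)
    energy <- energy + sum(pw[win][!taken[win]])
    taken[win] <- TRUE
    if (energy / total >= peak_energy) break
    if (length(centers) > max_peaks) return("broadband")
  }
  if (energy / total < peak_energy) return("broadband")
  # harmonic relationship: all cluster frequencies near integer multiples
  # of the lowest one
  f <- sort(sp$freq[centers])
  ratio <- f / f[1]
  if (all(abs(ratio - round(ratio)) < 0.15)) "discrete-peaks" else "broadband"
}

decide_label <- function(min_biomass, cv, verdict, lambda,
                         extinct_threshold = 1e-4, cv_threshold = 1e-3,
                         lambda_threshold = 1e-3, spectrum_first = FALSE) {
  if (!is.na(min_biomass) && min_biomass < extinct_threshold) return("extinct")
  if (cv < cv_threshold || verdict == "monotonic") return("stationary")
  # staged indicators: a purely discrete (harmonic) spectrum identifies
  # periodic dynamics before the Lyapunov split -- used when lambda comes
  # from the bias-prone embedding estimator rather than the model equations
  if (spectrum_first && verdict == "discrete-peaks") return("periodic")
  if (!is.na(lambda) && lambda < lambda_threshold) return("periodic")
  if (is.na(lambda)) return("periodic")
  "chaotic"
}

new_classification <- function(label, cv, lambda, verdict, min_biomass) {
  structure(list(label = label, cv = cv, lambda_max = lambda,
                 spectral_verdict = verdict, min_biomass = min_biomass),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("label: %s  (CV = %.4g, lambda = %s /d, spectrum: %s, min biomass = %.3g)\n",
              x$label, x$cv,
              if (is.na(x$lambda_max)) "NA" else sprintf("%+.5f", x$lambda_max),
              x$spectral_verdict, x$min_biomass))
  invisible(x)
}

#' Classify a food-web trajectory
#'
#' Approach-1 identification of the dynamical regime of a simulated
#' trajectory using three indicators over the last `window_years`:
#' \enumerate{
#'   \item a solution with any biotic pool below `1e-4` mgC m^-3 is
#'     `"extinct"` (no longer experimentally observable);
#'   \item otherwise it is `"stationary"` if the largest per-pool CV is
#'     below `1e-3` or the spectrum is monotonic;
#'   \item otherwise it is `"periodic"` if the maximal Lyapunov exponent is
#'     below `1e-3` day^-1, and `"chaotic"` otherwise.
#' }
#' The Lyapunov exponent is recomputed through the model equations
#' ([foodweb_lyapunov()]); for stochastic forcing it is reported as `NA`
#' (the Wolf estimate is not meaningful under noise -- use
#' [detect_chaos_cep()] instead) and the periodic/chaotic split falls back
#' to `"periodic"`.
#'
#' @param x a `foodweb_trajectory` from [integrate_foodweb()].
#' @param window_years analysis window (years). Default 10.
#' @param lambda_measure_years measurement span of the Lyapunov estimate
#'   (years). Default 60.
#' @return A `classification` object with fields `label`, `cv`,
#'   `lambda_max`, `spectral_verdict`, `min_biomass`.
#' @export
classify_trajectory <- function(x, window_years = 10,
                                lambda_measure_years = 60) {
  stopifnot(inherits(x, "foodweb_trajectory"))
  if (x$years < window_years)
    stop("trajectory shorter than the analysis window", call. = FALSE)
  w <- trajectory_window(x, window_years)
  bio <- w$state[, 1:5, drop = FALSE]
  min_biomass <- min(bio)
  cvs <- apply(bio, 2, function(s) if (mean(s) > 0)
    coefficient_of_variation(s) else 0)
  cv <- max(cvs)
  focal <- bio[, which.max(cvs)]
  verdict <- spectral_verdict(focal)
  lambda <- if (x$forcing$kind == "deterministic") {
    foodweb_lyapunov(x$config, x$forcing$seasonal,
                     transient_years = max(x$years - window_years, 10),
                     measure_years = lambda_measure_years,
                     steps_per_year = x$steps_per_year)
  } else NA_real_
  new_classification(decide_label(min_biomass, cv, verdict, lambda),
                     cv, lambda, verdict, min_biomass)
}

#' Classify an externally supplied series
#'
#' Applies the same indicator thresholds to a bare time series: CV,
#' spectral verdict, and (unless supplied) an embedding-based Wolf
#' Lyapunov estimate. No extinction rule is applied unless biomass
#' semantics are requested via `extinct_threshold`.
#'
#' @param series numeric vector on a uniform grid.
#' @param dt sampling interval in the series' time unit. Default 1.
#' @param lambda optional precomputed Lyapunov exponent (per time unit);
#'   when `NULL` it is estimated with [lyapunov_wolf_series()].
#' @param extinct_threshold optional: treat `min(series)` below this as
#'   extinct. Default `NA` (rule disabled).
#' @return A `classification` object.
#' @export
classify_series <- function(series, dt = 1, lambda = NULL,
                            extinct_threshold = NA) {
  cv <- coefficient_of_variation(series)
  verdict <- spectral_verdict(series)
  estimated <- is.null(lambda)
  if (estimated && cv >= 1e-3 && verdict %in% "broadband") {
    lambda <- tryCatch(lyapunov_wolf_series(series, dt = dt),
                       error = function(e) NA_real_)
  } else if (is.null(lambda)) lambda <- NA_real_
  mb <- if (is.na(extinct_threshold)) NA_real_ else min(series)
  new_classification(
    decide_label(if (is.na(extinct_threshold)) NA else mb, cv, verdict,
                 lambda,
                 extinct_threshold = if (is.na(extinct_threshold)) 0
                 else extinct_threshold, spectrum_first = estimated),
    cv, lambda, verdict, mb)
}
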