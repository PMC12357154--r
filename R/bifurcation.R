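#' Envelope extrema of a series
#'
#' Local maxima and minima of the terminal analysis window, thinned so
#' consecutive retained maxima (and, separately, minima) are at least
#' `min_separation` days apart. Thinning is greedy by extremity: on a
#' conflict the more extreme value is kept. Plateaus count once, at their
#' midpoint. A series with no interior extremum (constant or monotone over
#' the window) yields its overall maximum and minimum, one value each.
#'
#' @param series numeric vector.
#' @param times sample times (days), uniform grid.
#' @param min_separation minimum time between retained extrema of the same
#'   kind (days). Default 30.
#' @param window_years terminal window analyzed (years). Default 10; use
#'   `NULL` for the whole series.
#' @return List with numeric vectors `maxima`, `minima` (values), and
#'   `t_max`, `t_min` (their times).
#' @export
envelope_extrema <- function(series, times, min_separation = 30,
                             window_years = 10) {
  stopifnot(length(series) == length(times))
  if (!is.null(window_years)) {
    t_end <- times[length(times)]
    keep <- times > t_end - window_years * 365 + 1e-9
    if (!any(keep)) stop("window longer than series", call. = FALSE)
    series <- series[keep]
    times <- times[keep]
  }
  n <- length(series)
  if (n < 3L) stop("series too short", call. = FALSE)
  d <- diff(series)
  sgn <- sign(d)
  # collapse plateaus: carry the last nonzero slope through flat runs,
  # remembering where the flat run started so plateaus count at midpoint
  idx_max <- integer(0)
  idx_min <- integer(0)
  last_sgn <- 0
  flat_start <- NA_integer_
  for (i in seq_len(n - 1L)) {
    s <- sgn[i]
    if (s == 0) {
      if (is.na(flat_start)) flat_start <- i
      next
    }
    pos <- if (!is.na(flat_start)) (flat_start + i) %/% 2L else i
    if (last_sgn > 0 && s < 0) idx_max <- c(idx_max, pos)
    if (last_sgn < 0 && s > 0) idx_min <- c(idx_min, pos)
    last_sgn <- s
    flat_start <- NA_integer_
  }
  if (!length(idx_max) && !length(idx_min)) {
    return(list(maxima = max(series), minima = min(series),
                t_max = times[which.max(series)],
                t_min = times[which.min(series)]))
  }
  thin <- function(idx, decreasing) {
    if (!length(idx)) return(integer(0))
    ord <- idx[order(series[idx], decreasing = decreasing)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) ||
          all(abs(times[i] - times[kept]) >= min_separation)) {
        kept <- c(kept, i)
      }
    }
    sort(kept)
  }
  km <- thin(idx_max, TRUE)
  kn <- thin(idx_min, FALSE)
  list(maxima = series[km], minima = series[kn],
       t_max = times[km], t_min = times[kn])
}

# collapse values equal within relative tolerance to one representative
collapse_values <- function(v, rel_tol = 1e-4) {
  if (length(v) <= 1L) return(v)
  v <- sort(v)
  scale <- max(abs(v), 1e-12)
  out <- v[1]
  for (x in v[-1]) if (abs(x - out[length(out)]) > rel_tol * scale)
    out <- c(out, x)
  out
}

#' Bifurcation diagram over the seasonal amplitude
#'
#' For each amplitude `A_y` of the annual temperature cycle, simulates the
#' food web, extracts per-pool envelope extrema from the last
#' `window_years` (30-day separation rule), collapses extrema equal within
#' `rel_tol`, and flags the amplitude as chaotic when the maximal Lyapunov
#' exponent exceeds `1e-3` day^-1. A fixed point yields one plotted value
#' per pool, a limit cycle finitely many, chaos a filled band.
#'
#' @param config a [foodweb_config()].
#' @param amplitudes amplitude grid (degrees C). Default `0:15`.
#' @param years,steps_per_year simulation grid. Defaults 20 and 5000.
#' @param window_years envelope window (years). Default 10.
#' @param min_separation extremum separation (days). Default 30.
#' @param rel_tol point-collapse relative tolerance. Default 1e-4.
#' @param lambda_measure_years Lyapunov measurement span. Default 60.
#' @param pools pools included. Default the five biotic pools.
#' @return A `bifurcation_diagram`: list with `points` (data frame:
#'   `amplitude`, `pool`, `type`, `value`, `chaotic`), `lambda` (per
#'   amplitude), `failed` (amplitudes whose integration failed), `config`.
#' @export
build_bifurcation <- function(config, amplitudes = 0:15, years = 20,
                              steps_per_year = 5000, window_years = 10,
                              min_separation = 30, rel_tol = 1e-4,
                              lambda_measure_years = 60,
                              pools = c("P1", "P2", "Z1", "Z2", "B")) {
  amplitudes <- sort(amplitudes)
  rows <- list()
  lambdas <- numeric(0)
  failed <- numeric(0)
  for (A in amplitudes) {
    sp <- seasonal_params(A_y = A)
    tr <- tryCatch(integrate_foodweb(config, sp, years = years,
                                     steps_per_year = steps_per_year),
                   error = function(e) NULL)
    if (is.null(tr)) {
      failed <- c(failed, A)
      next
    }
    lam <- foodweb_lyapunov(config, sp,
                            transient_years = max(years - window_years, 10),
                            measure_years = lambda_measure_years,
                            steps_per_year = steps_per_year)
    lambdas[as.character(A)] <- lam
    chaotic <- lam > 1e-3
    for (pl in pools) {
      ee <- envelope_extrema(tr$state[, pl], tr$times,
                             min_separation = min_separation,
                             window_years = window_years)
      mx <- collapse_values(ee$maxima, rel_tol)
      mn <- collapse_values(ee$minima, rel_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        amplitude = A, pool = pl,
        type = rep(c("max", "min"), c(length(mx), length(mn))),
        value = c(mx, mn), chaotic = chaotic)
    }
  }
  structure(list(points = do.call(rbind, rows), lambda = lambdas,
                 failed = failed, config = config,
                 amplitudes = amplitudes),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation diagram: %d amplitudes, %d plotted points\n",
              length(x$amplitudes), nrow(x$points)))
  ch <- names(x$lambda)[x$lambda > 1e-3]
  cat(sprintf("  chaotic amplitudes (lambda > 1e-3): %s\n",
              if (length(ch)) paste(ch, collapse = ", ") else "none"))
  if (length(x$failed))
    cat("  failed amplitudes:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, pool = "P1", log = "", ...) {
  pts <- x$points[x$points$pool == pool, ]
  plot(pts$amplitude, pts$value, pch = 20, cex = 0.5,
       col = ifelse(pts$chaotic, "#3366CC", "#EE8800"),
       xlab = expression(A[y] ~ "(" * degree * "C)"),
       ylab = sprintf("%s envelope extrema (mgC m-3)", pool), log = log, ...)
  invisible(x)
}

#' Write bifurcation points as CSV
#' @param x a `bifurcation_diagram`.
#' @param file output path; columns `amplitude, pool, type, value, chaotic`.
#' @return `file`, invisibly.
#' @export
write_bifurcation_csv <- function(x, file) {
  utils::write.csv(x$points, file, row.names = FALSE)
  invisible(file)
}
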