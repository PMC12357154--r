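#' Ordinal pattern of a window
#'
#' Maps `d` consecutive (delay-spaced) values to their Bandt-Pompe ordinal
#' pattern: the 1-based indices of the values sorted ascending, so
#' `(4.2, 3.1, 5.6)` maps to `(2, 1, 3)`. Ties are broken by original
#' position (stable), and the pattern is invariant under any strictly
#' increasing transformation of the values.
#'
#' @param window numeric vector of length `d`.
#' @return Integer permutation of `seq_along(window)`.
#' @export
#' @examples
#' ordinal_pattern(c(4.2, 3.1, 5.6))
ordinal_pattern <- function(window) {
  if (anyNA(window)) stop("window contains NA", call. = FALSE)
  order(window)
}

#' Ordinal-pattern probability distribution
#'
#' Slides a window of `d` values spaced `eps` samples apart along the
#' series (unit stride, overlapping windows), ranks each window into its
#' ordinal pattern and tabulates relative frequencies. The number of
#' windows is `N - (d - 1) * eps`; patterns never observed carry
#' probability zero but still count toward the alphabet size `M = d!`.
#'
#' @param series numeric vector.
#' @param d embedding dimension (window length). Default 6.
#' @param eps embedding delay in samples (>= 1). Default 1.
#' @return An `ordinal_distribution`: list with `p` (named vector of
#'   observed-pattern frequencies), `d`, `eps`, `M = factorial(d)`,
#'   `n_windows`.
#' @export
ordinal_probabilities <- function(series, d = 6, eps = 1) {
  d <- as.integer(d); eps <- as.integer(eps)
  if (d < 2L) stop("'d' must be >= 2", call. = FALSE)
  if (eps < 1L) stop("'eps' must be >= 1", call. = FALSE)
  n <- length(series)
  n_win <- n - (d - 1L) * eps
  if (n_win < 1L)
    stop(sprintf("series too short: need at least %d samples for d=%d, eps=%d",
                 (d - 1L) * eps + 1L, d, eps), call. = FALSE)
  # stable within-window ranks via pairwise comparisons, vectorized over
  # all windows at once; the rank vector identifies the pattern uniquely
  base <- seq_len(n_win)
  cols <- lapply(0:(d - 1L), function(j) series[base + j * eps])
  id <- numeric(n_win)   # pattern id = sum (rank_i - 1) * d^(i-1)
  pw <- 1
  for (i in seq_len(d)) {
    ri <- numeric(n_win) # rank_i - 1 = number of elements before x_i
    for (j in seq_len(d)) {
      if (i == j) next
      ri <- ri + if (j < i) (cols[[j]] <= cols[[i]]) else (cols[[j]] < cols[[i]])
    }
    id <- id + ri * pw
    pw <- pw * d
  }
  counts <- table(id)
  structure(list(p = as.numeric(counts) / n_win,
                 pattern_id = as.numeric(names(counts)),
                 d = d, eps = eps, M = factorial(d), n_windows = n_win),
            class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("Ordinal distribution: d = %d, eps = %d, %d/%d patterns observed over %d windows\n",
              x$d, x$eps, length(x$p), x$M, x$n_windows))
  invisible(x)
}

# accept either an ordinal_distribution or a bare probability vector with
# alphabet size M
as_prob <- function(dist, M = NULL) {
  if (inherits(dist, "ordinal_distribution")) list(p = dist$p, M = dist$M)
  else {
    p <- as.numeric(dist)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("probabilities must be nonnegative and sum to 1", call. = FALSE)
    list(p = p[p > 0], M = if (is.null(M)) length(p) else M)
  }
}

shannon <- function(p) -sum(p[p > 0] * log(p[p > 0]))

#' Permutation entropy
#'
#' Normalized Shannon entropy of an ordinal-pattern distribution,
#' `HS = S(p) / ln(M)` with `M = d!`, so that a monotone series scores 0
#' and white noise scores (asymptotically) 1.
#'
#' @param dist an [ordinal_probabilities()] result, or a bare probability
#'   vector.
#' @param M alphabet size when `dist` is a bare vector (default its length).
#' @return `HS` in `[0, 1]`.
#' @export
permutation_entropy <- function(dist, M = NULL) {
  pr <- as_prob(dist, M)
  shannon(pr$p) / log(pr$M)
}

# maximal Jensen-Shannon divergence to the uniform distribution over M
# symbols, attained by a degenerate (delta) distribution
max_js_divergence <- function(M) {
  -0.5 * ((M + 1) / M * log(M + 1) - 2 * log(2 * M) + log(M))
}

js_divergence_uniform <- function(p, M) {
  # J(p, pe) = S((p+pe)/2) - S(p)/2 - S(pe)/2 with pe uniform over M;
  # symbols with p_i = 0 contribute 1/(2M) each to the mixture
  k <- length(p)
  mix <- (p + 1 / M) / 2
  s_mix <- shannon(mix) + (M - k) * (1 / (2 * M)) * log(2 * M)
  s_mix - shannon(p) / 2 - log(M) / 2
}

#' Permutation statistical complexity
#'
#' Jensen-Shannon statistical complexity
#' `CJS = Q0 * J(p, pe) * HS(p)`, where `J` is the Jensen-Shannon
#' divergence between the pattern distribution and the uniform distribution
#' `pe`, `Q0 = 1/max(J)` normalizes the disequilibrium to `[0, 1]`, and
#' `HS` is the permutation entropy. Both the uniform and the degenerate
#' distribution score 0; distributions halfway between order and disorder
#' score high.
#'
#' @inheritParams permutation_entropy
#' @return `CJS >= 0`.
#' @export
statistical_complexity <- function(dist, M = NULL) {
  pr <- as_prob(dist, M)
  hs <- shannon(pr$p) / log(pr$M)
  q0 <- 1 / max_js_divergence(pr$M)
  q0 * js_divergence_uniform(pr$p, pr$M) * hs
}

#' Bounding curves of the complexity-entropy plane
#'
#' For a fixed alphabet size `M`, every probability distribution maps to a
#' point `(HS, CJS)` between two curves. The lower bound is traced by
#' distributions uniform except for one elevated symbol; the upper bound by
#' distributions uniform on a subset of `n*` symbols with one partially
#' filled extra symbol (swept over `n*` and the filling), following the
#' standard geometric construction of the plane.
#'
#' @param M alphabet size (>= 2). For ordinal patterns `M = d!`.
#' @param n_grid points per family segment. Default 200.
#' @return A `complexity_bounds` object: list of data frames `lower` and
#'   `upper`, each with columns `HS`, `CJS` sorted by `HS`.
#' @export
complexity_bounds <- function(M, n_grid = 200) {
  stopifnot(M >= 2)
  q0 <- 1 / max_js_divergence(M)
  eval_pt <- function(p) {
    hs <- shannon(p) / log(M)
    c(HS = hs, CJS = q0 * js_divergence_uniform(p, M) * hs)
  }
  # lower bound: one symbol at a in [1/M, 1], the rest share 1 - a
  a <- seq(1 / M, 1, length.out = max(n_grid * 4L, 800L))
  lower <- t(vapply(a, function(ai)
    eval_pt(c(ai, rep((1 - ai) / (M - 1), M - 1L))), c(HS = 0, CJS = 0)))
  lower <- as.data.frame(lower)
  lower <- lower[order(lower$HS), ]
  # upper bound: n* equal symbols at b plus the remainder on one symbol,
  # b in [1/(n*+1), 1/n*]; endpoints are the uniform-on-subset points
  ups <- lapply(seq_len(M - 1L), function(ns) {
    b <- seq(1 / (ns + 1), 1 / ns, length.out = n_grid)
    t(vapply(b, function(bi) {
      p <- c(rep(bi, ns), 1 - ns * bi)
      eval_pt(p[p > 0])
    }, c(HS = 0, CJS = 0)))
  })
  upper <- as.data.frame(do.call(rbind, ups))
  upper <- upper[order(upper$HS), ]
  upper <- upper[!duplicated(upper$HS), ]
  structure(list(lower = lower, upper = upper, M = M),
            class = "complexity_bounds")
}

#' Interpolate the bound curves at given entropy values
#'
#' @param bounds a [complexity_bounds()] object.
#' @param HS entropy values in `[0, 1]`.
#' @return Data frame with `HS`, `CJS_min`, `CJS_max`.
#' @export
bounds_at <- function(bounds, HS) {
  stopifnot(inherits(bounds, "complexity_bounds"))
  lo <- stats::approx(bounds$lower$HS, bounds$lower$CJS, xout = HS,
                      rule = 2)$y
  hi <- stats::approx(bounds$upper$HS, bounds$upper$CJS, xout = HS,
                      rule = 2)$y
  data.frame(HS = HS, CJS_min = lo, CJS_max = hi)
}

#' Remove the periodic (seasonal) component of a series
#'
#' Subtracts the multi-year climatology: the mean over years of the values
#' observed at the same phase of the period. Requires at least two full
#' periods; the sampling step must divide the period.
#'
#' @param series numeric vector on a uniform grid.
#' @param times sample times (days), uniform.
#' @param period period to remove (days). Default 365.
#' @return Residual series (same length).
#' @export
deseasonalize <- function(series, times, period = 365) {
  dt <- times[2] - times[1]
  spp <- round(period / dt)
  if (abs(spp * dt - period) > 1e-6 * period)
    stop("sampling step does not divide the period", call. = FALSE)
  if (length(series) < 2L * spp)
    stop("need at least two full periods to estimate the climatology",
         call. = FALSE)
  phase <- ((seq_along(series) - 1L) %% spp)
  clim <- stats::ave(series, phase)
  series - clim
}

#' Multiscale complexity-entropy causality curve
#'
#' Computes the permutation entropy and statistical complexity of a series
#' for a set of embedding delays, tracing the parametric curve in the
#' complexity-entropy causality plane. Different delays probe different
#' time scales of the dynamics. Bound curves at the matching entropies are
#' attached.
#'
#' @param series numeric vector (deseasonalize first when a seasonal cycle
#'   is superimposed; see [deseasonalize()]).
#' @param d embedding dimension. Default 6.
#' @param delays integer vector of embedding delays (samples). Default: a
#'   geometric grid of ~20 delays from 1 sample up to `max_delay`.
#' @param max_delay largest default delay; defaults to one quarter of the
#'   usable series length and is capped so every delay keeps at least
#'   `d! / 2` windows.
#' @param bounds optional precomputed [complexity_bounds()] for `M = d!`.
#' @return A `cep_curve`: data frame with `eps`, `HS`, `CJS`, `CJS_min`,
#'   `CJS_max`, plus attributes `d` and `bounds`.
#' @export
cep_curve <- function(series, d = 6, delays = NULL, max_delay = NULL,
                      bounds = NULL) {
  n <- length(series)
  if (is.null(max_delay))
    max_delay <- max(1L, floor((n - factorial(d) / 2) / (d - 1) / 4))
  if (is.null(delays)) {
    delays <- unique(round(exp(seq(log(1), log(max_delay), length.out = 20))))
  }
  delays <- sort(unique(as.integer(delays)))
  usable <- delays[n - (d - 1L) * delays >= max(10L, d)]
  if (!length(usable)) stop("series too short for every delay", call. = FALSE)
  if (is.null(bounds)) bounds <- complexity_bounds(factorial(d))
  rows <- lapply(usable, function(e) {
    dist <- ordinal_probabilities(series, d = d, eps = e)
    hs <- permutation_entropy(dist)
    cj <- statistical_complexity(dist)
    c(eps = e, HS = hs, CJS = cj)
  })
  out <- as.data.frame(do.call(rbind, rows))
  bd <- bounds_at(bounds, out$HS)
  out$CJS_min <- bd$CJS_min
  out$CJS_max <- bd$CJS_max
  structure(out, class = c("cep_curve", "data.frame"), d = d, bounds = bounds)
}

#' Chaos / noise verdict from a complexity-entropy curve
#'
#' Implements the multiscale decision rule: a series is called chaotic when
#' at some embedding delay the permutation entropy falls in
#' `hs_window` while the statistical complexity comes within a tolerance of
#' the maximum complexity attainable at that entropy, and the curve passes
#' the necessary shape condition (a maximum of `CJS` over delays accompanied
#' by locally increasing `HS`). White noise scores entropy near 1 with
#' complexity near 0 at every delay; colored (time-correlated) noise sits at
#' intermediate entropy away from the maximal-complexity curve; strongly
#' ordered (periodic/monotone) series score low entropy.
#'
#' @param curve a [cep_curve()].
#' @param hs_window entropy window for the chaos test. Default
#'   `c(0.45, 0.70)`.
#' @param tol_frac "near the maximum" tolerance, as a fraction of
#'   `CJS_max(HS)`. Default 0.05.
#' @param hs_white entropy above which (with `CJS <= cjs_white`) a delay
#'   looks like white noise. Default 0.9.
#' @param cjs_white complexity threshold for the white-noise region.
#'   Default 0.1.
#' @return A `cep_verdict`: list with `verdict` in
#'   `{"chaotic", "colored-noise", "white-noise", "regular"}`,
#'   `supporting_delays`, and the thresholds used.
#' @export
detect_chaos_cep <- function(curve, hs_window = c(0.45, 0.70),
                             tol_frac = 0.05, hs_white = 0.9,
                             cjs_white = 0.1) {
  stopifnot(inherits(curve, "cep_curve"))
  if (nrow(curve) < 3L) stop("need a curve with >= 3 delays", call. = FALSE)
  near_max <- curve$CJS >= curve$CJS_max * (1 - tol_frac)
  in_window <- curve$HS >= hs_window[1] & curve$HS <= hs_window[2]
  # necessary shape condition: delays at (or tied within 2% of) the CJS
  # maximum over the curve, with HS increasing through that scale
  cmax <- max(curve$CJS)
  at_max <- curve$CJS >= cmax * 0.98
  hs_incr <- vapply(seq_len(nrow(curve)), function(i) {
    lo <- if (i > 1L) curve$HS[i] >= curve$HS[i - 1L] else TRUE
    hi <- if (i < nrow(curve)) curve$HS[i + 1L] >= curve$HS[i] else TRUE
    lo && hi
  }, logical(1))
  chaos_delays <- curve$eps[near_max & in_window & at_max & hs_incr]
  if (length(chaos_delays)) {
    v <- "chaotic"; sup <- chaos_delays
  } else if (min(curve$HS) < hs_window[1]) {
    v <- "regular"; sup <- curve$eps[curve$HS < hs_window[1]]
  } else if (all(curve$HS >= hs_white & curve$CJS <= cjs_white)) {
    v <- "white-noise"; sup <- curve$eps
  } else {
    v <- "colored-noise"; sup <- curve$eps[curve$HS < hs_white]
  }
  structure(list(verdict = v, supporting_delays = sup,
                 hs_window = hs_window, tol_frac = tol_frac,
                 hs_white = hs_white, cjs_white = cjs_white),
            class = "cep_verdict")
}

#' @export
print.cep_verdict <- function(x, ...) {
  cat(sprintf("CEP verdict: %s (supported at %d delay%s)\n", x$verdict,
              length(x$supporting_delays),
              if (length(x$supporting_delays) == 1L) "" else "s"))
  invisible(x)
}

#' @export
plot.cep_curve <- function(x, ...) {
  bounds <- attr(x, "bounds")
  plot(bounds$upper$HS, bounds$upper$CJS, type = "l", col = "grey40",
       xlab = expression(H[S]), ylab = expression(C[JS]),
       main = "Complexity-entropy causality plane", ...)
  graphics::lines(bounds$lower$HS, bounds$lower$CJS, col = "grey40")
  graphics::points(x$HS, x$CJS, pch = 19,
                   col = grDevices::hcl.colors(nrow(x), "viridis"))
  graphics::lines(x$HS, x$CJS, col = "grey70")
  invisible(x)
}
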