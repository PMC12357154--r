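#' Calibrated endogenous-regime presets
#'
#' Returns a [foodweb_config()] calibrated so that the unforced model
#' (constant temperature, no noise) expresses one of the three endogenous
#' regimes:
#' \describe{
#'   \item{ES}{endogenous stationary: trajectory converges to a fixed point.}
#'   \item{EP}{endogenous periodic: a stable limit cycle.}
#'   \item{EC}{endogenous chaotic: aperiodic dynamics with a positive
#'     maximal Lyapunov exponent (> 10^-3 per day).}
#' }
#' The three presets differ only in the initial phosphate load `PO4_0`
#' (the bifurcation parameter of the nutrient-enrichment path) with the
#' shared excreted fraction `beta_z = 0.60`; the remaining food-web
#' parameters are the single calibrated set held by [foodweb_config()]
#' defaults. The calibrated loads are 0.03 (ES), 0.055 (EP) and 0.07 (EC)
#' mmol P m^-3.
#'
#' @param name one of `"ES"`, `"EP"`, `"EC"`.
#' @param ... overrides passed on to [foodweb_config()].
#' @return A `foodweb_config`.
#' @export
#' @examples
#' cls <- classify_trajectory(integrate_foodweb(preset_config("EP"),
#'                            seasonal_params(A_y = 0), years = 20))
#' cls$label
preset_config <- function(name = c("ES", "EP", "EC"), ...) {
  name <- match.arg(name)
  PO4 <- switch(name, ES = 0.03, EP = 0.055, EC = 0.07)
  foodweb_config(PO4_0 = PO4, beta_z = 0.60, ...)
}
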