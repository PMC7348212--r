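#' Cathodic oxygen reduction rate attributable to cable bacteria
#'
#' The difference between the total diffusive O2 uptake of a sediment with an
#' active cable-bacteria population and that of a matched sediment without
#' one. The standard deviation of the difference is combined additively by
#' default (the conservative convention used for the incubation contrast);
#' quadrature is the statistically standard alternative.
#'
#' @param withCB O2 uptake with cable bacteria, mmol O2 m-2 d-1.
#' @param withoutCB O2 uptake without cable bacteria, mmol O2 m-2 d-1.
#' @param sdWith,sdWithout standard deviations of the two rates (optional).
#' @param sdMode `"additive"` (default) or `"quadrature"`.
#' @return list with `rate` (the difference), `sd`, `fraction` (percent of
#'   the total uptake attributed to cathodic reduction) and `warning` (TRUE
#'   when the difference is negative: no cable-bacteria signal).
#' @examples
#' cathodicRate(35.1, 21.6, sdWith = 7.7, sdWithout = 3.7)
#' @export
cathodicRate <- function(withCB, withoutCB, sdWith = NA_real_,
                         sdWithout = NA_real_,
                         sdMode = c("additive", "quadrature")) {
  sdMode <- match.arg(sdMode)
  if (withCB < 0 || withoutCB < 0) stop("rates must be >= 0")
  diff <- withCB - withoutCB
  sd <- if (is.na(sdWith) || is.na(sdWithout)) NA_real_
        else if (sdMode == "additive") sdWith + sdWithout
        else sqrt(sdWith^2 + sdWithout^2)
  warn <- diff < 0
  if (warn) warning("negative difference: no cable-bacteria O2 signal")
  list(rate = diff, sd = sd, fraction = esoxFraction(diff, withCB),
       warning = warn)
}

#' Fraction of total oxygen uptake attributable to e-SOx
#'
#' @param cathodic cathodic O2 reduction rate, mmol O2 m-2 d-1.
#' @param total total O2 uptake of the electrogenic sediment, mmol O2 m-2 d-1.
#' @return percentage of the total uptake.
#' @export
esoxFraction <- function(cathodic, total) {
  if (total <= 0) stop("total uptake must be > 0")
  100 * cathodic / total
}

#' Current density from cathodic oxygen reduction
#'
#' Cathodic O2 reduction transfers 4 electrons per O2 molecule; the electron
#' flux converts to a current density through the Faraday constant.
#'
#' @param cathodicO2 cathodic O2 reduction rate, mmol O2 m-2 d-1.
#' @param sd optional standard deviation of the rate (propagated linearly).
#' @return a [CurrentDensity-class] with `source = "cathodic_O2"`.
#' @examples
#' currentValue(currentFromO2(13.6)) # ~61 mA m-2
#' @export
currentFromO2 <- function(cathodicO2, sd = NA_real_) {
  if (cathodicO2 < 0) stop("cathodic O2 rate must be >= 0")
  eflux <- 4 * cathodicO2
  new("CurrentDensity", value = electronFluxToCurrent(eflux),
      source = "cathodic_O2", electronFlux = eflux,
      sd = if (is.na(sd)) NA_real_ else electronFluxToCurrent(4 * sd))
}

#' Anodic sulfide budget
#'
#' Sums the three sulfide sources consumed by anodic sulfide oxidation:
#' the upward sulfide flux from the deep sulfidic zone, sulfate reduction
#' within the suboxic zone -- estimated by scaling the deep production by the
#' ratio of zone widths, assuming a uniform volumetric sulfate reduction rate
#' -- and sulfide freed by net FeS dissolution, taken equal to the upward
#' Fe2+ flux (1:1 stoichiometry; the downward Fe2+ flux is assumed to
#' re-precipitate as FeS and is not counted).
#'
#' @param jUpSulfide upward sulfide flux, mmol H2S m-2 d-1.
#' @param wSuboxic suboxic zone width, mm.
#' @param wSulfidic sulfidic zone width, mm.
#' @param jFeS sulfide from net FeS dissolution (upward Fe2+ flux magnitude),
#'   mmol m-2 d-1; may be 0.
#' @return a [SulfideBudget-class].
#' @examples
#' totalAnodic(sulfideBudget(4.8, 10, 59, 2.0)) # ~7.6 mmol H2S m-2 d-1
#' @export
sulfideBudget <- function(jUpSulfide, wSuboxic, wSulfidic, jFeS = 0) {
  if (wSulfidic <= 0) stop("sulfidic zone width must be > 0")
  if (wSuboxic < 0) stop("suboxic zone width must be >= 0")
  if (jUpSulfide < 0 || jFeS < 0) stop("fluxes must be >= 0")
  sr <- wSuboxic / wSulfidic * jUpSulfide
  new("SulfideBudget", jUpSulfide = jUpSulfide, wSuboxic = wSuboxic,
      wSulfidic = wSulfidic, srSuboxic = sr, jFeS = jFeS,
      totalAnodic = jUpSulfide + sr + jFeS)
}

#' Current density from anodic sulfide oxidation
#'
#' Oxidation of sulfide to sulfate releases 8 electrons per sulfide; the
#' total anodic sulfide consumption therefore fixes the current density the
#' filaments must carry.
#'
#' @param budget a [SulfideBudget-class].
#' @param sd optional standard deviation of the total rate.
#' @return a [CurrentDensity-class] with `source = "anodic_S"`.
#' @export
currentFromSulfide <- function(budget, sd = NA_real_) {
  stopifnot(is(budget, "SulfideBudget"))
  eflux <- 8 * budget@totalAnodic
  new("CurrentDensity", value = electronFluxToCurrent(eflux),
      source = "anodic_S", electronFlux = eflux,
      sd = if (is.na(sd)) NA_real_ else electronFluxToCurrent(8 * sd))
}

setMethod("show", "SulfideBudget", function(object) {
  cat("Anodic sulfide budget (mmol H2S m-2 d-1)\n")
  cat(sprintf("  upward flux from sulfidic zone: %0.3g\n", object@jUpSulfide))
  cat(sprintf("  suboxic-zone sulfate reduction: %0.3g (width ratio %g/%g)\n",
              object@srSuboxic, object@wSuboxic, object@wSulfidic))
  cat(sprintf("  net FeS dissolution:            %0.3g\n", object@jFeS))
  cat(sprintf("  total anodic consumption:       %0.3g\n", object@totalAnodic))
})

setMethod("show", "CurrentDensity", function(object) {
  lab <- if (object@source == "cathodic_O2") "cathodic O2 reduction"
         else "anodic sulfide oxidation"
  cat(sprintf("CurrentDensity from %s: %0.4g mA m-2", lab, object@value))
  if (!is.na(object@sd)) cat(sprintf(" (sd %0.3g)", object@sd))
  cat(sprintf("\n  electron flux %0.4g mmol e- m-2 d-1\n", object@electronFlux))
})
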