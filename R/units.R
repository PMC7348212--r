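## Centralized unit conversions. All rates in mmol m-2 d-1, currents in mA m-2.

.FARADAY <- 96485.33212   # C mol-1
.SECONDS_PER_DAY <- 86400

#' Convert an areal electron flux into a current density
#'
#' One mole of electrons per day corresponds to F / 86400 ampere, with F the
#' Faraday constant. Equivalently 1 A transports about 1.036e-5 mol e- s-1.
#'
#' @param eflux electron flux, mmol e- m-2 d-1.
#' @return current density, mA m-2.
#' @examples
#' electronFluxToCurrent(54.4) # cathodic side of a 13.6 mmol O2 flux
#' @export
electronFluxToCurrent <- function(eflux) {
  stopifnot(is.numeric(eflux))
  eflux * 1e-3 * .FARADAY / .SECONDS_PER_DAY * 1e3
}

#' Tortuosity correction factor for sediment diffusion
#'
#' The effective diffusivity in porous sediment is reduced by the factor
#' `1 - 2 ln(porosity)`; it equals 1 in free solution (porosity 1) and grows
#' as porosity decreases.
#'
#' @param phi porosity, fraction in (0, 1].
#' @return unitless factor >= 1.
#' @export
tortuosityFactor <- function(phi) {
  if (any(phi <= 0 | phi > 1)) stop("porosity must be in (0, 1]")
  1 - 2 * log(phi)
}

## Molecular diffusion coefficients (m2 d-1) at the incubation conditions
## (16 degC, salinity 30), from standard seawater diffusivity tables.
## Always overridable: every flux function takes D explicitly.
.D_DEFAULTS <- c(O2 = 1.38e-4, H2S = 1.10e-4, SumH2S = 1.10e-4, Fe = 4.9e-5)

#' Default molecular diffusion coefficients
#'
#' Packaged free-solution diffusion coefficients for O2, H2S and Fe2+ at
#' 16 degrees C and salinity 30 (standard seawater tables). These are
#' conveniences only: every flux computation takes `D` as an explicit
#' argument, so site-specific values can always be supplied.
#'
#' @param analyte one of `"O2"`, `"H2S"`, `"SumH2S"`, `"Fe"`.
#' @return diffusion coefficient, m2 d-1.
#' @export
diffusionCoefficient <- function(analyte = c("O2", "H2S", "SumH2S", "Fe")) {
  analyte <- match.arg(analyte)
  unname(.D_DEFAULTS[analyte])
}
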