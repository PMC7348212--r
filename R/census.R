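#' Construct census parameters
#'
#' @param lCell mean cell length, micrometres (default 3).
#' @param nCopy 16S rRNA gene copies per cell (default 2).
#' @param rhoW wet bulk density, g cm-3 (default 1.32).
#' @param lCB colonization depth of cable bacteria, cm (default 1.5).
#' @return a [CensusParams-class].
#' @export
CensusParams <- function(lCell = 3, nCopy = 2, rhoW = 1.32, lCB = 1.5) {
  new("CensusParams", lCell = lCell, nCopy = nCopy, rhoW = rhoW, lCB = lCB)
}

#' Cell and filament densities from a 16S copy density
#'
#' Converts a qPCR copy density (copies per gram of wet sediment) into:
#' cells per cm3 (`C * rho_w / n_copy`); volumetric filament length density
#' `N_F,volume = C * L_cell * rho_w / n_copy` (metres of filament per cm3);
#' areal filament length density `N_F,area = N_F,volume * L_CB` by
#' depth-integration over the colonized interval; the areal filament count
#' under the straight-vertical-filament assumption (each filament spans
#' `L_CB`, so `count = N_F,area / L_CB = N_F,volume` numerically per cm2);
#' and the mean horizontal spacing for a square (`d = n^-1/2`) or hexagonal
#' (`d = (2 / (sqrt(3) n))^1/2`) arrangement of filaments.
#'
#' @param cQPCR 16S copy density, copies per g wet sediment (>= 0).
#' @param params a [CensusParams-class].
#' @param lattice spacing model, `"hexagonal"` (default) or `"square"`.
#' @return a [FilamentCensus-class].
#' @examples
#' filamentCensus(3e8)  # ~600 m cm-3, ~900 m cm-2, ~6e4 filaments cm-2
#' @export
filamentCensus <- function(cQPCR, params = CensusParams(),
                           lattice = c("hexagonal", "square")) {
  lattice <- match.arg(lattice)
  stopifnot(is(params, "CensusParams"))
  if (cQPCR < 0) stop("copy density must be >= 0")
  cells_cm3 <- cQPCR * params@rhoW / params@nCopy
  ## cells cm-3 x um per cell -> um cm-3; 1e-6 gives m cm-3
  nf_volume <- cells_cm3 * params@lCell * 1e-6
  nf_area <- nf_volume * params@lCB
  count <- nf_area / (params@lCB * 1e-2)   # filament length L_CB cm -> m
  spacing <- if (count > 0) {
    d_cm <- if (lattice == "square") sqrt(1 / count)
            else sqrt(2 / (sqrt(3) * count))
    d_cm * 1e4
  } else NA_real_
  new("FilamentCensus", copyDensity = cQPCR, cellDensity = cells_cm3,
      nfVolume = nf_volume, nfArea = nf_area, filamentCount = count,
      spacing = spacing, lattice = lattice)
}

setMethod("show", "FilamentCensus", function(object) {
  cat("FilamentCensus\n")
  cat(sprintf("  16S copy density:    %0.3g copies (g wet)-1\n", object@copyDensity))
  cat(sprintf("  cell density:        %0.3g cells cm-3\n", object@cellDensity))
  cat(sprintf("  filament length:     %0.3g m cm-3 | %0.3g m cm-2\n",
              object@nfVolume, object@nfArea))
  cat(sprintf("  filament count:      %0.3g cm-2\n", object@filamentCount))
  cat(sprintf("  mean spacing:        %0.3g um (%s lattice)\n",
              object@spacing, object@lattice))
})

#' Electric current carried by an average single filament
#'
#' Divides an areal current density by the areal filament count.
#'
#' @param currentDensity current density, mA m-2, or a
#'   [CurrentDensity-class].
#' @param filamentCountArea filaments per cm2 (> 0), or a
#'   [FilamentCensus-class].
#' @return current per filament, pA.
#' @examples
#' filamentCurrent(61, 6e4)  # ~102 pA per filament
#' @export
filamentCurrent <- function(currentDensity, filamentCountArea) {
  if (is(currentDensity, "CurrentDensity")) currentDensity <- currentDensity@value
  if (is(filamentCountArea, "FilamentCensus"))
    filamentCountArea <- filamentCountArea@filamentCount
  if (filamentCountArea <= 0) stop("filament count must be > 0")
  ## mA m-2 -> A m-2; filaments cm-2 -> m-2; A -> pA
  currentDensity * 1e-3 / (filamentCountArea * 1e4) * 1e12
}

#' Cell-specific oxygen consumption rate
#'
#' Divides the cathodic O2 reduction rate by the cable-bacteria cell
#' inventory of the oxic zone -- only cells within the oxygen penetration
#' depth reduce oxygen -- and expresses the result per cell and day.
#'
#' @param cathodicO2 cathodic O2 reduction rate, mmol O2 m-2 d-1.
#' @param opd oxygen penetration depth, mm (> 0).
#' @param cellDensity volumetric cell density, cells cm-3 (> 0), or a
#'   [FilamentCensus-class].
#' @return fmol O2 per cell per day.
#' @examples
#' cellSpecificO2(13.6, 1, filamentCensus(3e8))  # ~69 fmol O2 cell-1 d-1
#' @export
cellSpecificO2 <- function(cathodicO2, opd, cellDensity) {
  if (is(cellDensity, "FilamentCensus")) cellDensity <- cellDensity@cellDensity
  if (opd <= 0) stop("oxygen penetration depth must be > 0")
  if (cellDensity <= 0) stop("oxic-zone cell density must be > 0")
  ## cells per m2 in the oxic layer: cells cm-3 x opd (mm -> cm) x 1e4 cm2 m-2
  inventory <- cellDensity * (opd / 10) * 1e4
  ## mmol m-2 d-1 -> fmol cell-1 d-1: 1 mmol = 1e12 fmol
  cathodicO2 * 1e12 / inventory
}

#' Growth timing from a fold increase in abundance
#'
#' The number of doublings is `log2(fold)`; combined with a doubling time it
#' dates the onset of population growth.
#'
#' @param fold fold increase in copy density (> 0).
#' @param doublingTime doubling time, hours (> 0).
#' @return list with `nDoublings` (raw), `nDoublingsRounded`, and
#'   `daysElapsed` (rounded doublings times doubling time, in days).
#' @examples
#' growthTiming(78, 20)  # ~6 doublings, ~5 days
#' @export
growthTiming <- function(fold, doublingTime) {
  if (fold <= 0) stop("fold increase must be > 0")
  if (doublingTime <= 0) stop("doubling time must be > 0")
  n <- log2(fold)
  nr <- round(n)
  list(nDoublings = n, nDoublingsRounded = nr,
       daysElapsed = nr * doublingTime / 24)
}
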