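#' @import methods
NULL

.PROFILE_ANALYTES <- c("O2", "H2S", "SumH2S", "pH")
.QPCR_TARGETS <- c("TB", "DSB", "CB")

#' DepthProfile: one analyte's pore-water concentration versus depth
#'
#' Holds a microsensor depth profile together with the environmental metadata
#' (temperature, salinity, porosity) needed downstream for flux estimation.
#' Depth is in millimetres, zero at the sediment-water interface, positive
#' downward; negative depths are overlying water. Concentrations are in
#' micromolar for dissolved gases; pH on the total scale.
#'
#' @slot analyte one of `"O2"`, `"H2S"`, `"SumH2S"`, `"pH"`.
#' @slot depth numeric, mm, strictly increasing, at least 3 points.
#' @slot value numeric, same length as `depth`.
#' @slot temperature numeric(1), degrees Celsius.
#' @slot salinity numeric(1), practical salinity (unitless).
#' @slot porosity numeric(1), volume fraction in (0, 1].
#'
#' @seealso [DepthProfile()] for the user constructor.
#' @export
setClass("DepthProfile",
  representation(
    analyte = "character",
    depth = "numeric",
    value = "numeric",
    temperature = "numeric",
    salinity = "numeric",
    porosity = "numeric"
  ),
  prototype(temperature = 16, salinity = 30, porosity = 0.88)
)

setValidity("DepthProfile", function(object) {
  msg <- character()
  if (length(object@analyte) != 1L || !object@analyte %in% .PROFILE_ANALYTES)
    msg <- c(msg, sprintf("analyte must be one of %s",
                          paste(.PROFILE_ANALYTES, collapse = ", ")))
  if (length(object@depth) < 3L)
    msg <- c(msg, "at least 3 depth points required")
  if (length(object@depth) != length(object@value))
    msg <- c(msg, "depth and value must have equal length")
  if (anyNA(object@depth) || is.unsorted(object@depth, strictly = TRUE))
    msg <- c(msg, "depth must be strictly increasing and free of NA")
  if (length(object@analyte) == 1L && object@analyte %in% .PROFILE_ANALYTES) {
    if (object@analyte == "pH") {
      if (any(object@value <= 0 | object@value >= 14, na.rm = TRUE))
        msg <- c(msg, "pH values must lie in (0, 14)")
    } else if (any(object@value < 0, na.rm = TRUE)) {
      msg <- c(msg, "concentrations must be non-negative")
    }
  }
  if (length(object@porosity) != 1L || is.na(object@porosity) ||
      object@porosity <= 0 || object@porosity > 1)
    msg <- c(msg, "porosity must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' FluxEstimate: a diffusive flux fitted from a depth profile
#'
#' Result of [fickFlux()]. The flux `J` is signed with positive pointing
#' downward into the sediment, so a consumption profile (concentration
#' decreasing with depth) yields a positive downward flux.
#'
#' @slot J numeric(1), mmol m-2 d-1, positive downward.
#' @slot slope numeric(1), fitted concentration gradient, umol L-1 mm-1.
#' @slot D numeric(1), molecular diffusion coefficient, m2 d-1.
#' @slot tortuosityFactor numeric(1), 1 - 2 ln(porosity), >= 1.
#' @slot window numeric(2), depth interval (mm) used for the fit.
#' @slot r2 numeric(1), coefficient of determination of the fit.
#' @slot analyte character(1), analyte of the source profile.
#' @slot n integer(1), number of points in the fit window.
#' @export
setClass("FluxEstimate",
  representation(
    J = "numeric", slope = "numeric", D = "numeric",
    tortuosityFactor = "numeric", window = "numeric",
    r2 = "numeric", analyte = "character", n = "integer"
  )
)

setValidity("FluxEstimate", function(object) {
  msg <- character()
  if (!is.na(object@tortuosityFactor) && object@tortuosityFactor < 1)
    msg <- c(msg, "tortuosity factor must be >= 1 for porosity <= 1")
  if (length(object@window) != 2L)
    msg <- c(msg, "window must be a depth interval of length 2")
  if (length(msg)) msg else TRUE
})

#' Zonation: oxic / suboxic / sulfidic layering of a sediment profile
#'
#' Result of [detectZonation()]. A suboxic zone -- where both oxygen and free
#' sulfide are below detection -- is the geochemical fingerprint of electrogenic
#' sulfur oxidation by cable bacteria. Quantities are `NA` when undefined
#' (e.g. oxygen never drops below the threshold).
#'
#' @slot opd numeric(1), oxygen penetration depth, mm (NA if undefined).
#' @slot sulfideAppearance numeric(1), depth where total sulfide first exceeds
#'   the detection threshold, mm (NA if never).
#' @slot suboxicWidth numeric(1), `sulfideAppearance - opd`, floored at 0, mm.
#' @slot phMax numeric(2), `(depth, pH)` of the subsurface pH maximum.
#' @slot phMin numeric(2), `(depth, pH)` of the deep pH minimum.
#' @slot threshold numeric(1), detection threshold used, umol L-1.
#' @export
setClass("Zonation",
  representation(
    opd = "numeric", sulfideAppearance = "numeric", suboxicWidth = "numeric",
    phMax = "numeric", phMin = "numeric", threshold = "numeric"
  )
)

setValidity("Zonation", function(object) {
  msg <- character()
  if (!is.na(object@suboxicWidth) && object@suboxicWidth < 0)
    msg <- c(msg, "suboxic width cannot be negative")
  if (length(msg)) msg else TRUE
})

#' SulfideBudget: anodic sulfide source terms for the electron balance
#'
#' The three sources of sulfide consumed by anodic sulfide oxidation: the
#' upward flux from the deep sulfidic zone, sulfate reduction within the
#' suboxic zone (scaled from the deep flux by the zone-width ratio), and
#' sulfide liberated by net FeS dissolution (equal to the upward Fe2+ flux,
#' 1:1 stoichiometry). All rates in mmol H2S m-2 d-1.
#'
#' @slot jUpSulfide numeric(1), upward sulfide flux from the sulfidic zone.
#' @slot wSuboxic numeric(1), suboxic zone width, mm.
#' @slot wSulfidic numeric(1), sulfidic (sulfate-reducing) zone width, mm.
#' @slot srSuboxic numeric(1), derived suboxic-zone sulfate reduction rate.
#' @slot jFeS numeric(1), sulfide from net FeS dissolution.
#' @slot totalAnodic numeric(1), sum of the three source terms.
#' @export
setClass("SulfideBudget",
  representation(
    jUpSulfide = "numeric", wSuboxic = "numeric", wSulfidic = "numeric",
    srSuboxic = "numeric", jFeS = "numeric", totalAnodic = "numeric"
  )
)

setValidity("SulfideBudget", function(object) {
  msg <- character()
  if (object@wSulfidic <= 0) msg <- c(msg, "sulfidic zone width must be > 0")
  if (object@wSuboxic < 0) msg <- c(msg, "suboxic zone width must be >= 0")
  if (object@jUpSulfide < 0 || object@jFeS < 0)
    msg <- c(msg, "sulfide source fluxes must be >= 0")
  sr <- object@wSuboxic / object@wSulfidic * object@jUpSulfide
  if (abs(object@srSuboxic - sr) > 1e-9 * max(1, abs(sr)))
    msg <- c(msg, "srSuboxic inconsistent with width ratio times upward flux")
  tot <- object@jUpSulfide + object@srSuboxic + object@jFeS
  if (abs(object@totalAnodic - tot) > 1e-9 * max(1, abs(tot)))
    msg <- c(msg, "totalAnodic must equal the sum of the three source terms")
  if (length(msg)) msg else TRUE
})

#' CurrentDensity: areal electric current carried by cable bacteria
#'
#' An electron flux (mmol e- m-2 d-1) and its expression as a current density
#' (mA m-2) via the Faraday constant. Produced by [currentFromO2()] (cathodic
#' side, 4 e- per O2) or [currentFromSulfide()] (anodic side, 8 e- per sulfide
#' oxidized to sulfate).
#'
#' @slot value numeric(1), mA m-2, non-negative.
#' @slot source `"cathodic_O2"` or `"anodic_S"`.
#' @slot electronFlux numeric(1), mmol e- m-2 d-1.
#' @slot sd numeric(1), standard deviation in mA m-2 (NA when unknown).
#' @export
setClass("CurrentDensity",
  representation(
    value = "numeric", source = "character",
    electronFlux = "numeric", sd = "numeric"
  ),
  prototype(sd = NA_real_)
)

setValidity("CurrentDensity", function(object) {
  msg <- character()
  if (!object@source %in% c("cathodic_O2", "anodic_S"))
    msg <- c(msg, "source must be 'cathodic_O2' or 'anodic_S'")
  if (object@value < 0) msg <- c(msg, "current density must be >= 0")
  expected <- electronFluxToCurrent(object@electronFlux)
  if (abs(object@value - expected) > 1e-9 * max(1, expected))
    msg <- c(msg, "value inconsistent with electronFlux (Faraday conversion)")
  if (length(msg)) msg else TRUE
})

#' CalibrationCurve: fitted qPCR standard curve
#'
#' The log-linear relation Cq = intercept + slope * log10(copies), fitted to a
#' dilution series of standards. The amplification efficiency derives from the
#' slope as `10^(-1/slope) - 1`; a slope of -1/log10(2) = -3.3219 corresponds
#' to perfect doubling (efficiency 1).
#'
#' @slot slope numeric(1), Cq per log10(copies); negative for a valid curve.
#' @slot intercept numeric(1), Cq at 1 copy per microlitre.
#' @slot efficiency numeric(1), fraction (1 = 100 percent).
#' @slot r2 numeric(1), coefficient of determination.
#' @slot nStandards integer(1), number of standard reactions fitted.
#' @slot target character(1), `"TB"`, `"DSB"` or `"CB"`.
#' @export
setClass("CalibrationCurve",
  representation(
    slope = "numeric", intercept = "numeric", efficiency = "numeric",
    r2 = "numeric", nStandards = "integer", target = "character"
  ),
  prototype(target = "CB")
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@slope >= 0) msg <- c(msg, "slope must be negative for a valid curve")
  eff <- 10^(-1 / object@slope) - 1
  if (abs(object@efficiency - eff) > 1e-9 * max(1, eff))
    msg <- c(msg, "efficiency inconsistent with slope")
  if (!object@target %in% .QPCR_TARGETS)
    msg <- c(msg, "target must be one of TB, DSB, CB")
  if (length(msg)) msg else TRUE
})

#' SampleQuant: absolute quantification of one sample
#'
#' Replicate Cq values converted through a [CalibrationCurve-class] into
#' copies per microlitre of template and then -- via dilution factor, elution
#' volume and wet sediment mass -- into 16S copies per gram of wet sediment.
#'
#' @slot cq numeric, replicate Cq values.
#' @slot dilutionFactor numeric(1), fold dilution of the template.
#' @slot elutionVolume numeric(1), DNA elution volume, microlitres.
#' @slot wetMass numeric(1), extracted wet sediment mass, grams.
#' @slot copiesPerUl numeric(1), copies per microlitre of undiluted template.
#' @slot copyDensity numeric(1), copies per gram wet sediment.
#' @slot cv numeric(1), coefficient of variation of replicate copy estimates.
#' @slot belowDetection logical(1), TRUE when mean Cq exceeds the cutoff.
#' @slot target character(1), `"TB"`, `"DSB"` or `"CB"`.
#' @export
setClass("SampleQuant",
  representation(
    cq = "numeric", dilutionFactor = "numeric", elutionVolume = "numeric",
    wetMass = "numeric", copiesPerUl = "numeric", copyDensity = "numeric",
    cv = "numeric", belowDetection = "logical", target = "character"
  )
)

setValidity("SampleQuant", function(object) {
  msg <- character()
  if (object@wetMass <= 0) msg <- c(msg, "wet mass must be > 0")
  if (!is.na(object@copyDensity) && object@copyDensity < 0)
    msg <- c(msg, "copy density must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CensusParams: biological and physical parameters of the filament census
#'
#' Parameters converting 16S copy densities into cell and filament densities.
#' Defaults are the study conditions: 3 um cells, two 16S copies per cell
#' (as in the *Ca.* Electrothrix aarhusiensis genome), wet bulk density
#' 1.32 g cm-3 and colonization to 1.5 cm depth.
#'
#' @slot lCell numeric(1), mean cell length, micrometres.
#' @slot nCopy numeric(1), 16S rRNA gene copies per cell.
#' @slot rhoW numeric(1), wet bulk density, g cm-3.
#' @slot lCB numeric(1), colonization depth of cable bacteria, cm.
#' @export
setClass("CensusParams",
  representation(lCell = "numeric", nCopy = "numeric",
                 rhoW = "numeric", lCB = "numeric"),
  prototype(lCell = 3, nCopy = 2, rhoW = 1.32, lCB = 1.5)
)

setValidity("CensusParams", function(object) {
  vals <- c(object@lCell, object@nCopy, object@rhoW, object@lCB)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all census parameters must be finite and > 0" else TRUE
})

#' FilamentCensus: derived cell and filament densities
#'
#' Result of [filamentCensus()]. Volumetric filament length density follows
#' N_F,volume = C_qPCR x L_cell x rho_w / n_copy; areal density integrates it
#' over the colonization depth; the filament count assumes straight, vertical
#' filaments spanning that depth.
#'
#' @slot copyDensity numeric(1), 16S copies per g wet sediment.
#' @slot cellDensity numeric(1), cells per cm3 wet sediment.
#' @slot nfVolume numeric(1), filament length density, m cm-3.
#' @slot nfArea numeric(1), areal filament length density, m cm-2.
#' @slot filamentCount numeric(1), filaments per cm2.
#' @slot spacing numeric(1), mean horizontal inter-filament distance, um.
#' @slot lattice `"hexagonal"` or `"square"` spacing model.
#' @export
setClass("FilamentCensus",
  representation(
    copyDensity = "numeric", cellDensity = "numeric", nfVolume = "numeric",
    nfArea = "numeric", filamentCount = "numeric", spacing = "numeric",
    lattice = "character"
  )
)

setValidity("FilamentCensus", function(object) {
  msg <- character()
  if (!object@lattice %in% c("hexagonal", "square"))
    msg <- c(msg, "lattice must be 'hexagonal' or 'square'")
  if (any(c(object@copyDensity, object@cellDensity, object@nfVolume,
            object@nfArea, object@filamentCount) < 0, na.rm = TRUE))
    msg <- c(msg, "densities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DegeneratePrimer: an IUPAC-degenerate oligonucleotide
#'
#' A primer written 5' to 3' in the IUPAC nucleotide alphabet. Reverse primers
#' are given 5' to 3' on the reverse strand (the usual primer-table
#' convention); binding-site searches account for orientation.
#'
#' @slot name character(1), primer name.
#' @slot sequence character(1), IUPAC nucleotide string, length >= 10.
#' @slot orientation `"forward"` or `"reverse"`.
#'
#' @seealso [expandDegenerate()], [findBindingSites()], [primerQC()].
#' @export
setClass("DegeneratePrimer",
  representation(name = "character", sequence = "character",
                 orientation = "character")
)

setValidity("DegeneratePrimer", function(object) {
  msg <- character()
  seq <- toupper(object@sequence)
  if (length(seq) != 1L || nchar(seq) < 10L)
    msg <- c(msg, "primer sequence must be a single string of length >= 10")
  else if (!grepl("^[ACGTRYSWKMBDHVN]+$", seq))
    msg <- c(msg, "sequence contains characters outside the IUPAC alphabet")
  if (!object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  if (length(msg)) msg else TRUE
})

#' SpecificityReport: per-taxon primer and primer-pair hit counts
#'
#' Result of [specificityScreen()]: for each taxon in the reference set, the
#' number of templates hit at each allowed mismatch level, for each single
#' primer and (when a pair is screened) for the pair in productive orientation
#' within the amplicon length cap.
#'
#' @slot singleHits data.frame with columns `primer`, `taxon`,
#'   `max_mismatches`, `templates_hit`, `templates_total`.
#' @slot pairHits data.frame with columns `taxon`, `max_mismatches`,
#'   `templates_hit`, `templates_total` (zero rows for single-primer screens).
#' @slot levels integer, the mismatch levels screened.
#' @slot maxAmplicon numeric(1), amplicon length cap for pair hits, bp.
#' @slot excluded character, record ids lacking taxonomy (warned, excluded).
#' @export
setClass("SpecificityReport",
  representation(
    singleHits = "data.frame", pairHits = "data.frame",
    levels = "integer", maxAmplicon = "numeric", excluded = "character"
  )
)

#' ScenarioSpec: ground-truth description for the synthetic-data generator
#'
#' Everything the generators need to emit a full, internally consistent input
#' bundle: pore-water fingerprint parameters, planted copy-density profiles,
#' standard-curve parameters and noise levels. The electrogenic regime plants
#' the cable-bacteria fingerprint (suboxic zone, subsurface pH maximum, deep
#' pH minimum); the non-electrogenic regime has sulfide at the oxygen
#' penetration depth and no pH excursions.
#'
#' @slot regime `"electrogenic"` or `"non_electrogenic"`.
#' @slot opd numeric(1), planted oxygen penetration depth, mm.
#' @slot suboxicWidth numeric(1), planted suboxic zone width, mm.
#' @slot o2Uptake numeric(1), planted diffusive O2 uptake, mmol m-2 d-1.
#' @slot sulfideFlux numeric(1), planted upward sulfide flux, mmol m-2 d-1.
#' @slot phPeakAmplitude numeric(1), subsurface pH maximum above background.
#' @slot phMin numeric(1), deep pH minimum value.
#' @slot phMinDepth numeric(1), depth of the pH minimum, mm.
#' @slot phBackground numeric(1), overlying-water pH.
#' @slot porosity numeric(1), sediment porosity.
#' @slot temperature numeric(1), degrees C.
#' @slot salinity numeric(1).
#' @slot copyProfiles named list (per target TB/DSB/CB) of data.frames with
#'   columns `layer_top_cm`, `layer_bottom_cm`, `copies_per_g`.
#' @slot curveParams named list (per target) of `c(slope, intercept)`.
#' @slot cqNoiseSd numeric(1), Gaussian Cq noise, cycles.
#' @slot seed integer(1), master seed for all randomness.
#' @export
setClass("ScenarioSpec",
  representation(
    regime = "character", opd = "numeric", suboxicWidth = "numeric",
    o2Uptake = "numeric", sulfideFlux = "numeric",
    phPeakAmplitude = "numeric", phMin = "numeric", phMinDepth = "numeric",
    phBackground = "numeric", porosity = "numeric", temperature = "numeric",
    salinity = "numeric", copyProfiles = "list", curveParams = "list",
    cqNoiseSd = "numeric", seed = "integer"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (!object@regime %in% c("electrogenic", "non_electrogenic"))
    msg <- c(msg, "regime must be 'electrogenic' or 'non_electrogenic'")
  if (object@opd <= 0) msg <- c(msg, "opd must be > 0")
  if (object@suboxicWidth < 0) msg <- c(msg, "suboxic width must be >= 0")
  if (object@regime == "electrogenic" &&
      (object@suboxicWidth <= 0 || object@phPeakAmplitude <= 0))
    msg <- c(msg, "electrogenic regime requires suboxicWidth > 0 and phPeakAmplitude > 0")
  if (object@regime == "non_electrogenic" && object@suboxicWidth != 0)
    msg <- c(msg, "non-electrogenic regime requires suboxicWidth = 0")
  if (object@porosity <= 0 || object@porosity > 1)
    msg <- c(msg, "porosity must be in (0, 1]")
  if (length(msg)) msg else TRUE
})
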