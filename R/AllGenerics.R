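#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes, so user code never
#' touches slots directly.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("analyte", function(x) standardGeneric("analyte"))

#' @rdname accessors
#' @export
setGeneric("profileDepths", function(x) standardGeneric("profileDepths"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("porosity", function(x) standardGeneric("porosity"))

#' @rdname accessors
#' @export
setGeneric("fluxValue", function(x) standardGeneric("fluxValue"))

#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @rdname accessors
#' @export
setGeneric("copyDensity", function(x) standardGeneric("copyDensity"))

#' @rdname accessors
#' @export
setGeneric("degeneracy", function(x) standardGeneric("degeneracy"))

#' @rdname accessors
#' @export
setGeneric("primerSequence", function(x) standardGeneric("primerSequence"))

#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname accessors
#' @export
setGeneric("currentValue", function(x) standardGeneric("currentValue"))

#' @rdname accessors
#' @export
setGeneric("electronFlux", function(x) standardGeneric("electronFlux"))

#' @rdname accessors
#' @export
setGeneric("totalAnodic", function(x) standardGeneric("totalAnodic"))

#' @param object object to display.
#' @rdname accessors
setMethod("analyte", "DepthProfile", function(x) x@analyte)

#' @rdname accessors
setMethod("profileDepths", "DepthProfile", function(x) x@depth)

#' @rdname accessors
setMethod("profileValues", "DepthProfile", function(x) x@value)

#' @rdname accessors
setMethod("porosity", "DepthProfile", function(x) x@porosity)

#' @rdname accessors
setMethod("fluxValue", "FluxEstimate", function(x) x@J)

#' @rdname accessors
setMethod("efficiency", "CalibrationCurve", function(x) x@efficiency)

#' @rdname accessors
setMethod("copyDensity", "SampleQuant", function(x) x@copyDensity)

#' @rdname accessors
setMethod("copyDensity", "FilamentCensus", function(x) x@copyDensity)

#' @rdname accessors
setMethod("primerSequence", "DegeneratePrimer", function(x) x@sequence)

#' @rdname accessors
setMethod("orientation", "DegeneratePrimer", function(x) x@orientation)

#' @rdname accessors
setMethod("currentValue", "CurrentDensity", function(x) x@value)

#' @rdname accessors
setMethod("electronFlux", "CurrentDensity", function(x) x@electronFlux)

#' @rdname accessors
setMethod("totalAnodic", "SulfideBudget", function(x) x@totalAnodic)
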