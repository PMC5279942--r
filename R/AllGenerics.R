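#' @rdname accessors
#' @param object an object of one of the package's S4 classes.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))

#' @rdname accessors
#' @export
setGeneric("current", function(object) standardGeneric("current"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("stimulusOnset", function(object) standardGeneric("stimulusOnset"))

#' @rdname accessors
#' @export
setGeneric("holdingPotential", function(object) standardGeneric("holdingPotential"))

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setGeneric("traceTruth", function(object) standardGeneric("traceTruth"))

#' @rdname accessors
#' @export
setGeneric("pressures", function(object) standardGeneric("pressures"))

#' @rdname accessors
#' @export
setGeneric("peakCurrents", function(object) standardGeneric("peakCurrents"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))

#' Spring constant of a cylindrical elastomer pilus
#'
#' @param geom a [PillarGeometry-class] (or, for the numeric method, the
#'   modulus E in MPa with \code{r} and \code{L} supplied).
#' @param ... method-specific arguments.
#' @return spring constant k in pN/nm.
#' @export
setGeneric("springConstant", function(geom, ...) standardGeneric("springConstant"))
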