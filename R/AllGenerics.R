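#' @rdname TraceSet
#' @param object,x a TraceSet (or other calcimech object, for show methods).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname TraceSet
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname TraceSet
#' @export
setGeneric("stimFrame", function(x) standardGeneric("stimFrame"))
#' @rdname TraceSet
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname TraceSet
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname TraceSet
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname ForceCurve
#' @param x a ForceCurve.
#' @export
setGeneric("force", function(x) standardGeneric("force"))
#' @rdname ForceCurve
#' @export
setGeneric("piezoZ", function(x) standardGeneric("piezoZ"))

#' @rdname HertzFit
#' @param x a HertzFit.
#' @export
setGeneric("contactPoint", function(x) standardGeneric("contactPoint"))
#' @rdname HertzFit
#' @export
setGeneric("modulus", function(x) standardGeneric("modulus"))

#' @rdname SegmentationResult
#' @param x a SegmentationResult.
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname SegmentationResult
#' @export
setGeneric("labelAreas", function(x) standardGeneric("labelAreas"))
#' @rdname SegmentationResult
#' @export
setGeneric("labelCentroids", function(x) standardGeneric("labelCentroids"))

#' @rdname EphysGroup
#' @param x an EphysGroup.
#' @export
setGeneric("groupDensity", function(x) standardGeneric("groupDensity"))
#' @rdname EphysGroup
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname EphysGroup
#' @export
setGeneric("holdingPotential", function(x) standardGeneric("holdingPotential"))

setMethod("nFrames", "TraceSet", function(x) nrow(x@values))
setMethod("nCells", "TraceSet", function(x) ncol(x@values))
setMethod("stimFrame", "TraceSet", function(x) x@stimFrame)
setMethod("frameInterval", "TraceSet", function(x) x@dt)
setMethod("traceValues", "TraceSet", function(x) x@values)
setMethod("cellIds", "TraceSet", function(x) x@cellIds)

setMethod("show", "TraceSet", function(object) {
  cat(sprintf(
    "TraceSet: %d cells x %d frames (dt = %g s)\n  baseline frames 1-%d, stimulus before frame %d (%d post-stimulus frames)\n",
    ncol(object@values), nrow(object@values), object@dt,
    object@stimFrame - 1L, object@stimFrame,
    nrow(object@values) - object@stimFrame + 1L))
})

setMethod("show", "BaselineStats", function(object) {
  cat(sprintf("BaselineStats: mu = %.4g, sigma = %.4g, threshold = mu + %g sigma = %.4g\n",
              object@mu, object@sigma, object@kSigma, object@threshold))
})

setMethod("force", "ForceCurve", function(x) x@k * x@deflection)  # N/m * nm = nN
setMethod("piezoZ", "ForceCurve", function(x) x@z)

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf(
    "ForceCurve: %d points, z in [%.3g, %.3g] um, max force %.4g nN\n  probe: k = %.4g N/m, R = %.4g um, nu = %.3g\n",
    length(object@z), min(object@z), max(object@z),
    max(object@k * object@deflection), object@k, object@R, object@nu))
})

setMethod("contactPoint", "HertzFit", function(x) x@z0)
setMethod("modulus", "HertzFit", function(x) x@E)

setMethod("show", "HertzFit", function(object) {
  cat(sprintf(
    "HertzFit: E = %.4g kPa, z0 = %.4g um (window %g-%g%% of F_max, %d points, rms %.3g nN)\n",
    object@E, object@z0, 100 * object@window[1], 100 * object@window[2],
    object@nPoints, object@rms))
})

setMethod("show", "ImageStackPair", function(object) {
  d <- dim(object@green)
  cat(sprintf("ImageStackPair: %d x %d px, %d frames, two channels (green/red)\n",
              d[1], d[2], d[3]))
})

setMethod("labelImage", "SegmentationResult", function(x) x@labels)
setMethod("labelAreas", "SegmentationResult", function(x) x@areas)
setMethod("labelCentroids", "SegmentationResult", function(x) x@centroids)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d cells (min area %g px) in %d x %d px field\n",
              length(object@areas), object@minArea,
              nrow(object@labels), ncol(object@labels)))
})

setMethod("groupDensity", "EphysGroup", function(x) x@density)
setMethod("groupLabel", "EphysGroup", function(x) x@label)
setMethod("holdingPotential", "EphysGroup", function(x) x@voltage)

setMethod("show", "EphysGroup", function(object) {
  cat(sprintf("EphysGroup '%s' at %g mV: n = %d cells, mean density %.4g pA/pF\n",
              object@label, object@voltage, length(object@density),
              mean(object@density)))
})
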