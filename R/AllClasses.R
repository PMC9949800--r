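#' @import methods
NULL

#' TraceSet: per-cell ratiometric fluorescence over time
#'
#' Container for a set of single-cell ratiometric fluorescence traces
#' (e.g. Fluo-4 / Fura Red intensity ratios) sampled at a fixed frame
#' interval, together with the stimulus timing. Frames before
#' \code{stimFrame} are the baseline; \code{stimFrame} is the 1-based index
#' of the first post-stimulus frame (the stimulus event sits at the frame
#' boundary immediately before it).
#'
#' @slot values numeric matrix, frames x cells, dimensionless ratio.
#' @slot stimFrame integer(1), 1-based index of the first post-stimulus
#'   frame; at least 2 so that at least one baseline frame exists.
#' @slot dt numeric(1), seconds per frame.
#' @slot cellIds character vector of cell identifiers (column names).
#' @exportClass TraceSet
setClass("TraceSet",
  representation(
    values = "matrix",
    stimFrame = "integer",
    dt = "numeric",
    cellIds = "character"
  )
)

setValidity("TraceSet", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (any(!is.finite(v))) msgs <- c(msgs, "values must all be finite")
  if (length(object@stimFrame) != 1L ||
      object@stimFrame < 2L || object@stimFrame > nrow(v))
    msgs <- c(msgs, "stimFrame must lie in [2, n_frames]")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msgs <- c(msgs, "dt must be a positive scalar (seconds per frame)")
  if (length(object@cellIds) != ncol(v))
    msgs <- c(msgs, "cellIds length must equal the number of columns")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TraceSet
#'
#' @param values frames x cells numeric matrix of ratiometric fluorescence.
#' @param stimFrame 1-based index of the first post-stimulus frame.
#' @param dt frame interval in seconds.
#' @param cellIds optional cell identifiers; defaults to column names or
#'   \code{"cell_1"}, \code{"cell_2"}, ...
#' @return A \linkS4class{TraceSet}.
#' @examples
#' ts <- TraceSet(matrix(rnorm(40, 1, 0.05), 10, 4), stimFrame = 5, dt = 4)
#' nFrames(ts); nCells(ts)
#' @export
TraceSet <- function(values, stimFrame, dt, cellIds = NULL) {
  values <- as.matrix(values)
  if (is.null(cellIds)) {
    cellIds <- colnames(values)
    if (is.null(cellIds)) cellIds <- paste0("cell_", seq_len(ncol(values)))
  }
  colnames(values) <- cellIds
  new("TraceSet", values = values, stimFrame = as.integer(stimFrame),
      dt = as.numeric(dt), cellIds = as.character(cellIds))
}

#' BaselineStats: baseline mean, SD and response threshold
#'
#' Summary of a cell's pre-stimulus fluorescence: mean \code{mu}, sample
#' standard deviation \code{sigma} (n-1 denominator) and the responding
#' threshold \code{mu + kSigma * sigma} used for classification (default
#' kSigma = 3).
#'
#' @slot mu numeric(1) baseline mean (ratio units).
#' @slot sigma numeric(1) baseline sample SD.
#' @slot threshold numeric(1) responding threshold.
#' @slot kSigma numeric(1) SD multiplier used to form the threshold.
#' @exportClass BaselineStats
setClass("BaselineStats",
  representation(mu = "numeric", sigma = "numeric", threshold = "numeric",
                 kSigma = "numeric")
)

setValidity("BaselineStats", function(object) {
  if (object@sigma < 0) return("sigma must be non-negative")
  if (object@threshold < object@mu) return("threshold must be >= mu")
  TRUE
})

#' ForceCurve: a single AFM approach force curve
#'
#' Raw indentation record: piezo extension \code{z} (micrometres, increasing
#' toward the sample), cantilever deflection (nanometres), and probe
#' metadata. Force in nanonewtons is derived as \code{k * deflection}
#' (N/m times nm gives nN).
#'
#' @slot z numeric, piezo extension in micrometres, strictly increasing.
#' @slot deflection numeric, cantilever deflection in nanometres.
#' @slot k numeric(1), cantilever spring constant in N/m.
#' @slot R numeric(1), spherical tip radius in micrometres.
#' @slot nu numeric(1), sample Poisson's ratio in [0, 0.5].
#' @exportClass ForceCurve
setClass("ForceCurve",
  representation(z = "numeric", deflection = "numeric",
                 k = "numeric", R = "numeric", nu = "numeric")
)

setValidity("ForceCurve", function(object) {
  msgs <- character()
  if (length(object@z) != length(object@deflection))
    msgs <- c(msgs, "z and deflection must have equal length")
  if (length(object@z) >= 2 && any(diff(object@z) <= 0))
    msgs <- c(msgs, "z must be strictly increasing")
  if (any(!is.finite(object@z)) || any(!is.finite(object@deflection)))
    msgs <- c(msgs, "z and deflection must be finite")
  if (object@k <= 0) msgs <- c(msgs, "spring constant k must be positive")
  if (object@R <= 0) msgs <- c(msgs, "tip radius R must be positive")
  if (object@nu < 0 || object@nu > 0.5)
    msgs <- c(msgs, "Poisson's ratio nu must be in [0, 0.5]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ForceCurve
#'
#' @param z piezo extension (micrometres), strictly increasing.
#' @param deflection cantilever deflection (nanometres).
#' @param k spring constant (N/m).
#' @param R tip radius (micrometres).
#' @param nu Poisson's ratio (default 0.5, incompressible).
#' @return A \linkS4class{ForceCurve}.
#' @export
ForceCurve <- function(z, deflection, k, R, nu = 0.5) {
  new("ForceCurve", z = as.numeric(z), deflection = as.numeric(deflection),
      k = as.numeric(k), R = as.numeric(R), nu = as.numeric(nu))
}

#' HertzFit: fitted contact point and elastic modulus
#'
#' Result of fitting the spherical-indenter Hertz model
#' \eqn{F = (4/3) (E / (1 - \nu^2)) \sqrt{R} \delta^{3/2}} to a force curve,
#' with indentation \eqn{\delta = (z - z_0) - d} corrected for cantilever
#' deflection \eqn{d}.
#'
#' @slot z0 numeric(1), contact point (micrometres).
#' @slot E numeric(1), elastic modulus (kilopascals).
#' @slot window numeric(2), force-fraction window used for the fit.
#' @slot rms numeric(1), root-mean-square force residual (nanonewtons).
#' @slot nPoints integer(1), number of points used in the fit.
#' @exportClass HertzFit
setClass("HertzFit",
  representation(z0 = "numeric", E = "numeric", window = "numeric",
                 rms = "numeric", nPoints = "integer")
)

setValidity("HertzFit", function(object) {
  msgs <- character()
  if (object@E <= 0) msgs <- c(msgs, "E must be positive")
  if (!is.finite(object@rms)) msgs <- c(msgs, "residual rms must be finite")
  if (length(object@window) != 2 || object@window[1] >= object@window[2])
    msgs <- c(msgs, "window must be an increasing pair of force fractions")
  if (length(msgs)) msgs else TRUE
})

#' ImageStackPair: two-channel fluorescence time-lapse
#'
#' Green (Ca2+-sensitive) and red (reference) channel stacks as
#' \code{[Y, X, T]} arrays of non-negative intensities with identical
#' dimensions.
#'
#' @slot green numeric array [Y, X, T].
#' @slot red numeric array [Y, X, T].
#' @slot pixelSize numeric(1), micrometres per pixel; NA when uncalibrated.
#' @exportClass ImageStackPair
setClass("ImageStackPair",
  representation(green = "array", red = "array", pixelSize = "numeric")
)

setValidity("ImageStackPair", function(object) {
  msgs <- character()
  if (!identical(dim(object@green), dim(object@red)))
    msgs <- c(msgs, "green and red stacks must have identical dimensions")
  if (length(dim(object@green)) != 3)
    msgs <- c(msgs, "stacks must be 3-D arrays [Y, X, T]")
  if (any(!is.finite(object@green)) || any(!is.finite(object@red)))
    msgs <- c(msgs, "intensities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImageStackPair
#'
#' @param green,red numeric arrays [Y, X, T] of channel intensities.
#' @param pixelSize micrometres per pixel (NA when uncalibrated).
#' @return An \linkS4class{ImageStackPair}.
#' @export
ImageStackPair <- function(green, red, pixelSize = NA_real_) {
  new("ImageStackPair", green = green, red = red,
      pixelSize = as.numeric(pixelSize))
}

#' SegmentationResult: labelled cell regions
#'
#' Label image plus per-label geometry from thresholding + watershed of the
#' red-channel maximum projection. Labels are contiguous 1..N, numbered by
#' decreasing area (ties broken by centroid row, then column); 0 is
#' background.
#'
#' @slot labels integer matrix [Y, X]; 0 = background.
#' @slot areas integer vector, pixels per label.
#' @slot centroids numeric matrix N x 2 (row, col), 1-based pixel centres.
#' @slot minArea numeric(1), the size filter applied (pixels).
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(labels = "matrix", areas = "integer",
                 centroids = "matrix", minArea = "numeric")
)

setValidity("SegmentationResult", function(object) {
  msgs <- character()
  n <- length(object@areas)
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  if (n > 0 && !identical(labs, seq_len(n)))
    msgs <- c(msgs, "labels must be contiguous 1..N")
  if (n > 0 && any(object@areas < object@minArea))
    msgs <- c(msgs, "every labelled region must satisfy the size filter")
  if (nrow(object@centroids) != n)
    msgs <- c(msgs, "centroids must have one row per label")
  if (length(msgs)) msgs else TRUE
})

#' EphysGroup: per-cell whole-cell current densities for one group
#'
#' One cell line x condition x holding potential group of whole-cell
#' recordings, stored as current densities (pA/pF). Construct from raw
#' currents and capacitances or from pre-normalised densities.
#'
#' @slot label character(1), group label (line x condition).
#' @slot voltage numeric(1), holding potential in mV.
#' @slot density numeric, per-cell current density (pA/pF).
#' @exportClass EphysGroup
setClass("EphysGroup",
  representation(label = "character", voltage = "numeric",
                 density = "numeric")
)

setValidity("EphysGroup", function(object) {
  if (length(object@density) < 1) return("group must contain >= 1 cell")
  if (any(!is.finite(object@density))) return("densities must be finite")
  TRUE
})

#' Construct an EphysGroup
#'
#' Either supply \code{density} directly, or \code{current} (pA) together
#' with \code{capacitance} (pF), in which case densities are computed with
#' \code{\link{currentDensity}}.
#'
#' @param label group label, e.g. \code{"T89I:basal"}.
#' @param voltage holding potential (mV).
#' @param density per-cell current densities (pA/pF).
#' @param current per-cell whole-cell currents (pA).
#' @param capacitance per-cell membrane capacitances (pF), positive.
#' @return An \linkS4class{EphysGroup}.
#' @examples
#' g <- EphysGroup("WT:basal", -70, current = c(-120, -80), capacitance = c(20, 16))
#' groupDensity(g)
#' @export
EphysGroup <- function(label, voltage, density = NULL, current = NULL,
                       capacitance = NULL) {
  if (is.null(density)) {
    if (is.null(current) || is.null(capacitance))
      stop("supply either `density` or both `current` and `capacitance`")
    density <- currentDensity(current, capacitance)
  }
  new("EphysGroup", label = as.character(label), voltage = as.numeric(voltage),
      density = as.numeric(density))
}
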