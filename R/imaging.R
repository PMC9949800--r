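#' @importFrom EBImage medianFilter distmap watershed otsu
NULL

#' Ratio stack: median-filtered green / red
#'
#' Applies a per-frame 2-D median filter (square neighbourhood, default
#' radius 1 px = 3x3) to both channels, then divides green by red
#' pixelwise. Pixels whose filtered red intensity is at or below
#' \code{eps} times the red maximum are masked invalid (NA) rather than
#' clamped, so they are excluded from cell means downstream; a fully
#' masked frame raises a warning.
#'
#' The median filter is EBImage's constant-time histogram median, which
#' operates on [0, 1] data; channels are normalised by their global maximum
#' before filtering and rescaled after (quantisation error ~1e-5 relative).
#'
#' @param pair an \linkS4class{ImageStackPair}.
#' @param medianRadius median filter radius in pixels (default 1; 0 skips
#'   filtering).
#' @param eps invalid-pixel cutoff as a fraction of the red maximum
#'   (default 0.01, i.e. pixels with less than 1% of the peak reference
#'   intensity are treated as having no reference signal).
#' @return Array [Y, X, T] of ratios with NA at invalid pixels.
#' @export
ratioStack <- function(pair, medianRadius = 1, eps = 0.01) {
  g <- pair@green
  r <- pair@red
  nT <- dim(g)[3]
  if (medianRadius > 0) {
    gMax <- max(g); rMax <- max(r)
    for (t in seq_len(nT)) {
      if (gMax > 0)
        g[, , t] <- medianFilter(g[, , t] / gMax, medianRadius) * gMax
      if (rMax > 0)
        r[, , t] <- medianFilter(r[, , t] / rMax, medianRadius) * rMax
    }
  }
  cutoff <- eps * max(r)
  ratio <- g / r
  ratio[r <= cutoff] <- NA_real_
  for (t in seq_len(nT))
    if (all(is.na(ratio[, , t])))
      warning(sprintf("frame %d is fully masked (red channel ~ 0)", t))
  ratio
}

#' Segment cells from the red-channel maximum projection
#'
#' Reimplements the thresholding stage of the imaging pipeline: maximum
#' intensity projection of the red (reference) channel over time, global
#' threshold (Otsu by default), distance-transform watershed to split
#' touching cells, and a particle size filter discarding regions smaller
#' than \code{minArea} pixels (the "100-infinity" size gate). Labels are
#' renumbered 1..N by decreasing area, ties broken by centroid row then
#' column.
#'
#' @param x an \linkS4class{ImageStackPair}, or a [Y, X, T] red-channel
#'   array, or a single [Y, X] image.
#' @param thresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param thresholdValue absolute intensity cutoff when
#'   \code{thresholdMethod = "fixed"}.
#' @param minArea minimum region area in pixels (default 100).
#' @param wsTolerance watershed tolerance passed to
#'   \code{EBImage::watershed} (default 1, in distance-map units).
#' @return A \linkS4class{SegmentationResult}; zero labels is a valid
#'   result for an empty foreground.
#' @examples
#' g <- genImageStack(nCells = 4, shape = c(80, 80), radii = 8,
#'                    traceArgs = list(responderFrac = 0, nPre = 5,
#'                                     nPost = 5), seed = 1)
#' segmentCells(g$stack, minArea = 50)
#' @export
segmentCells <- function(x, thresholdMethod = c("otsu", "fixed"),
                         thresholdValue = NULL, minArea = 100,
                         wsTolerance = 1) {
  thresholdMethod <- match.arg(thresholdMethod)
  red <- if (is(x, "ImageStackPair")) x@red else x
  proj <- if (length(dim(red)) == 3) apply(red, c(1, 2), max) else red

  if (thresholdMethod == "otsu") {
    mx <- max(proj)
    th <- if (mx > 0) otsu(proj / mx, range = c(0, 1)) * mx else Inf
  } else {
    if (is.null(thresholdValue)) stop("thresholdValue required for fixed threshold")
    th <- thresholdValue
  }
  binary <- proj > th

  if (!any(binary)) {
    return(new("SegmentationResult",
               labels = matrix(0L, nrow(proj), ncol(proj)),
               areas = integer(0), centroids = matrix(0, 0, 2),
               minArea = minArea))
  }

  labels <- watershed(distmap(binary), tolerance = wsTolerance)
  labels <- matrix(as.integer(labels), nrow(proj), ncol(proj))

  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= minArea)
  # centroids for tie-breaking and reporting
  cen <- t(vapply(keep, function(l) {
    w <- which(labels == l, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  ord <- order(-tab[keep], cen[, 1], cen[, 2])
  keep <- keep[ord]
  cen <- cen[ord, , drop = FALSE]

  out <- matrix(0L, nrow(proj), ncol(proj))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  new("SegmentationResult", labels = out, areas = as.integer(tab[keep]),
      centroids = cen, minArea = minArea)
}

#' Extract per-cell mean ratio traces
#'
#' For every labelled cell and frame, the mean of the valid (non-NA) ratio
#' pixels inside the mask. Cells whose mask has no valid pixel in some
#' frame are dropped with a warning naming the cell.
#'
#' @param ratio [Y, X, T] ratio array from \code{\link{ratioStack}}.
#' @param seg a \linkS4class{SegmentationResult} matching the stack's
#'   spatial shape.
#' @param stimFrame 1-based index of the first post-stimulus frame.
#' @param dt frame interval (seconds).
#' @return A \linkS4class{TraceSet} (cells named \code{"cell_<label>"});
#'   an error if no cell survives.
#' @export
extractTraces <- function(ratio, seg, stimFrame, dt) {
  labs <- labelImage(seg)
  if (!identical(dim(labs), dim(ratio)[1:2]))
    stop("label image does not match the stack's spatial shape")
  nLab <- length(labelAreas(seg))
  if (nLab == 0) stop("segmentation contains no cells")
  nT <- dim(ratio)[3]
  flat <- matrix(ratio, ncol = nT)   # pixels x frames
  idxByLabel <- split(which(labs > 0), labs[labs > 0])

  traces <- vapply(seq_len(nLab), function(l) {
    colMeans(flat[idxByLabel[[as.character(l)]], , drop = FALSE], na.rm = TRUE)
  }, numeric(nT))

  ok <- apply(traces, 2, function(x) all(is.finite(x)))
  if (!all(ok))
    warning(sprintf("dropping %d cell(s) with no valid ratio pixels in some frame: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  if (!any(ok)) stop("no cell has valid ratio pixels in every frame")
  TraceSet(traces[, ok, drop = FALSE], stimFrame = stimFrame, dt = dt,
           cellIds = paste0("cell_", which(ok)))
}
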