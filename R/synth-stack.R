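#' Generate a synthetic two-channel image stack of disk-shaped cells
#'
#' Builds a two-channel time-lapse in which the red (reference dye) channel
#' is a constant disk per cell plus Gaussian noise, and the green channel is
#' the red channel multiplied by that cell's ratiometric trace from
#' \code{\link{genTraces}}. The ground-truth label image, the generating
#' traces and the responder mask are returned alongside, so segmentation and
#' trace extraction can be validated end to end.
#'
#' @param centers integer matrix n x 2 of disk centres (row, col), 1-based
#'   pixel coordinates; or NULL to auto-place \code{nCells} disks on a
#'   jittered grid (see \code{placeCells}).
#' @param radii disk radii in pixels (scalar or per-cell vector).
#' @param shape image size c(Y, X) in pixels.
#' @param nCells number of cells when \code{centers} is NULL.
#' @param redIntensity constant red-channel dye level inside cells.
#' @param noiseSigma additive Gaussian noise SD on both channels.
#' @param traceArgs list of arguments forwarded to \code{\link{genTraces}}
#'   (nCells and seed are filled in automatically).
#' @param seed integer RNG seed.
#' @return A list: \code{stack} (\linkS4class{ImageStackPair}), \code{truth}
#'   (list with \code{labels} matrix, \code{traces} TraceSet,
#'   \code{responder}, \code{latency}, \code{centers}, \code{radii},
#'   \code{touching} — a 2-column matrix of label pairs whose disks touch or
#'   overlap).
#' @examples
#' g <- genImageStack(nCells = 4, shape = c(80, 80), radii = 8,
#'                    traceArgs = list(responderFrac = 0.5, nPre = 10,
#'                                     nPost = 20), seed = 1)
#' max(g$truth$labels)
#' @export
genImageStack <- function(centers = NULL, radii = 10, shape = c(128L, 128L),
                          nCells = if (is.null(centers)) 5L else nrow(centers),
                          redIntensity = 1000, noiseSigma = 10,
                          traceArgs = list(responderFrac = 0.5),
                          seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(centers))
    centers <- placeCells(nCells, shape, max(radii))
  centers <- as.matrix(centers)
  nCells <- nrow(centers)
  radii <- rep_len(radii, nCells)
  if (any(centers[, 1] - radii < 1 | centers[, 1] + radii > shape[1] |
          centers[, 2] - radii < 1 | centers[, 2] + radii > shape[2]))
    stop("cells must lie fully within the image bounds")

  traceArgs$nCells <- nCells
  traceArgs$seed <- as.integer(seed) + 1L
  gt <- do.call(genTraces, traceArgs)
  ratios <- traceValues(gt$traces)            # frames x cells
  nFrames <- nrow(ratios)

  labels <- matrix(0L, shape[1], shape[2])
  rowIdx <- matrix(seq_len(shape[1]), shape[1], shape[2])
  colIdx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (i in seq_len(nCells)) {
    inside <- (rowIdx - centers[i, 1])^2 + (colIdx - centers[i, 2])^2 <=
      radii[i]^2
    labels[inside] <- i
  }

  # pairs of disks that touch or overlap (centre distance <= r_i + r_j)
  touching <- NULL
  if (nCells >= 2) {
    pr <- utils::combn(nCells, 2)
    d <- sqrt(colSums((t(centers)[, pr[1, ], drop = FALSE] -
                       t(centers)[, pr[2, ], drop = FALSE])^2))
    hit <- d <= radii[pr[1, ]] + radii[pr[2, ]]
    touching <- t(pr[, hit, drop = FALSE])
  }

  redFrame <- matrix(0, shape[1], shape[2])
  redFrame[labels > 0] <- redIntensity
  green <- red <- array(0, c(shape[1], shape[2], nFrames))
  cellRatio <- matrix(0, shape[1], shape[2])
  for (t in seq_len(nFrames)) {
    if (nCells > 0) cellRatio[labels > 0] <- ratios[t, labels[labels > 0]]
    red[, , t] <- redFrame +
      matrix(stats::rnorm(prod(shape), 0, noiseSigma), shape[1], shape[2])
    green[, , t] <- redFrame * cellRatio +
      matrix(stats::rnorm(prod(shape), 0, noiseSigma), shape[1], shape[2])
  }
  green[green < 0] <- 0
  red[red < 0] <- 0

  truth <- list(labels = labels, traces = gt$traces,
                responder = gt$truth$responder, latency = gt$truth$latency,
                centers = centers, radii = radii, touching = touching)
  list(stack = ImageStackPair(green, red), truth = truth)
}

#' Place non-overlapping cell centres on a jittered grid
#'
#' @param n number of cells.
#' @param shape image size c(Y, X).
#' @param radius disk radius in pixels.
#' @param margin extra spacing between disks (pixels, default 4).
#' @return n x 2 matrix of (row, col) centres.
#' @export
placeCells <- function(n, shape, radius, margin = 4) {
  pitch <- 2 * radius + margin
  ny <- floor((shape[1] - 2 * radius - 2) / pitch) + 1
  nx <- floor((shape[2] - 2 * radius - 2) / pitch) + 1
  if (ny * nx < n)
    stop(sprintf("cannot place %d cells of radius %g in a %d x %d image",
                 n, radius, shape[1], shape[2]))
  slots <- expand.grid(r = radius + 1 + pitch * (seq_len(ny) - 1),
                       c = radius + 1 + pitch * (seq_len(nx) - 1))
  pick <- slots[sample.int(nrow(slots), n), ]
  jit <- matrix(stats::runif(2 * n, -margin / 4, margin / 4), n, 2)
  ctr <- round(as.matrix(pick) + jit)
  ctr[, 1] <- pmin(pmax(ctr[, 1], radius + 1), shape[1] - radius)
  ctr[, 2] <- pmin(pmax(ctr[, 2], radius + 1), shape[2] - radius)
  unname(ctr)
}
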