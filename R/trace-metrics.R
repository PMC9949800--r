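#' Baseline statistics of a single calcium trace
#'
#' Mean and sample standard deviation (n-1 denominator) of the pre-stimulus
#' frames, and the responding threshold \code{mu + kSigma * sigma}.
#'
#' @param trace numeric vector, one cell's ratiometric trace.
#' @param stimFrame 1-based index of the first post-stimulus frame; frames
#'   \code{1:(stimFrame-1)} are baseline. At least 2 baseline frames are
#'   required for the SD.
#' @param kSigma SD multiplier for the threshold (default 3).
#' @return A \linkS4class{BaselineStats}.
#' @examples
#' baselineStats(c(1, 2, 3, 4, 5, 9, 9), stimFrame = 6)
#' @export
baselineStats <- function(trace, stimFrame, kSigma = 3) {
  if (stimFrame < 3 || stimFrame > length(trace) + 1L)
    stop("need at least 2 baseline frames before stimFrame")
  base <- trace[seq_len(stimFrame - 1L)]
  mu <- mean(base)
  sigma <- stats::sd(base)
  new("BaselineStats", mu = mu, sigma = sigma,
      threshold = mu + kSigma * sigma, kSigma = kSigma)
}

#' Classify a cell as responder or non-responder
#'
#' A post-stimulus frame is "responding" when its value strictly exceeds
#' the baseline threshold (mean + 3 SD by default). The cell is a responder
#' when at least a fraction \code{frac} (default 0.25, boundary inclusive)
#' of its post-stimulus frames respond.
#'
#' @param trace numeric vector, one cell's trace.
#' @param baseline a \linkS4class{BaselineStats} for this cell.
#' @param stimFrame 1-based index of the first post-stimulus frame.
#' @param frac minimum responding fraction of post-stimulus frames
#'   (default 0.25).
#' @return A list: \code{responder} (logical), \code{mask} (logical vector
#'   over post-stimulus frames), \code{frac} (observed responding fraction).
#' @export
classifyResponder <- function(trace, baseline, stimFrame, frac = 0.25) {
  post <- trace[stimFrame:length(trace)]
  if (length(post) < 1) stop("need at least 1 post-stimulus frame")
  mask <- post > baseline@threshold
  obs <- mean(mask)
  list(responder = obs >= frac, mask = mask, frac = obs)
}

#' Time of initial response of a responding cell
#'
#' The onset is the time of the first post-stimulus frame that starts a run
#' of at least two consecutive supra-threshold frames. The stimulus event
#' is placed at the frame boundary before \code{stimFrame}, so the first
#' post-stimulus frame has elapsed time \code{dt} (not 0): a run starting
#' at post-stimulus frame index f (1-based) has onset \code{f * dt}
#' seconds.
#'
#' @inheritParams classifyResponder
#' @param dt frame interval (seconds).
#' @return Onset time in seconds, or \code{NA_real_} when no run of two
#'   consecutive supra-threshold frames exists.
#' @export
responseTime <- function(trace, baseline, stimFrame, dt) {
  post <- trace[stimFrame:length(trace)]
  above <- post > baseline@threshold
  n <- length(above)
  if (n < 2) return(NA_real_)
  run2 <- which(above[-n] & above[-1])
  if (length(run2) == 0) return(NA_real_)
  run2[1] * dt
}

#' Peak-filtered area under a calcium trace
#'
#' Computes the area under the baseline-subtracted trace
#' \eqn{y(t) = \mathrm{value}(t) - \mu_b} over the post-stimulus window,
#' taking a baseline of Y = 0, counting only peaks that rise above the
#' baseline, and ignoring peaks whose height is less than
#' \code{minPeakFrac} (default 10\%) of the min-to-max range of y over the
#' window. A peak is a maximal run of frames with y > 0; its area is the
#' trapezoidal integral of the positive part of the piecewise-linear trace,
#' with zero crossings interpolated linearly.
#'
#' @inheritParams responseTime
#' @param minPeakFrac peaks with maximum height below this fraction of the
#'   window's min-to-max range are excluded (default 0.10).
#' @param window \code{"post"} (default) restricts the analysis to
#'   post-stimulus frames; \code{"full"} uses the whole trace.
#' @return Area in ratio x seconds (non-negative).
#' @examples
#' b <- new("BaselineStats", mu = 0, sigma = 0, threshold = 0, kSigma = 3)
#' traceAUC(c(0, rep(0, 4), rep(2, 10), rep(0, 5)), b, stimFrame = 2, dt = 1)
#' @export
traceAUC <- function(trace, baseline, stimFrame, dt, minPeakFrac = 0.10,
                     window = c("post", "full")) {
  window <- match.arg(window)
  if (minPeakFrac < 0 || minPeakFrac >= 1)
    stop("minPeakFrac must be in [0, 1)")
  idx <- if (window == "post") stimFrame:length(trace) else seq_along(trace)
  y <- trace[idx] - baseline@mu
  peakFilteredArea(y, dt, minPeakFrac)
}

# Area of the positive part of the piecewise-linear series y (spacing dt),
# keeping only maximal y>0 runs whose peak >= minPeakFrac * range(y).
peakFilteredArea <- function(y, dt, minPeakFrac) {
  n <- length(y)
  if (n == 0 || all(y <= 0)) return(0)
  rng <- max(y) - min(y)

  pos <- y > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keepRun <- runs$values & vapply(seq_along(runs$values), function(i) {
    runs$values[i] && max(y[starts[i]:ends[i]]) >= minPeakFrac * rng
  }, logical(1))

  total <- 0
  for (i in which(keepRun)) {
    a <- starts[i]; b <- ends[i]
    # interior panels of the run
    if (b > a) total <- total + sum((y[a:(b - 1)] + y[(a + 1):b]) / 2) * dt
    # boundary panels shared with the neighbouring non-positive frames
    if (a > 1) {
      y0 <- y[a - 1]; y1 <- y[a]
      total <- total + if (y0 >= 0) (y0 + y1) / 2 * dt
                       else y1^2 / (y1 - y0) / 2 * dt   # crossing triangle
    }
    if (b < n) {
      y1 <- y[b]; y0 <- y[b + 1]
      total <- total + if (y0 >= 0) (y0 + y1) / 2 * dt
                       else y1^2 / (y1 - y0) / 2 * dt
    }
  }
  total
}

#' Per-cell calcium-trace analysis of a TraceSet
#'
#' Runs \code{\link{baselineStats}}, \code{\link{classifyResponder}},
#' \code{\link{responseTime}} and \code{\link{traceAUC}} on every cell.
#'
#' @param ts a \linkS4class{TraceSet}.
#' @param kSigma threshold SD multiplier (default 3).
#' @param frac responder fraction rule (default 0.25).
#' @param minPeakFrac AUC peak-exclusion fraction (default 0.10).
#' @param aucWindow \code{"post"} or \code{"full"} (see
#'   \code{\link{traceAUC}}).
#' @return data.frame with one row per cell: \code{cell}, \code{mu},
#'   \code{sigma}, \code{threshold}, \code{respondingFrac},
#'   \code{responder}, \code{onset_s} (NA for non-responders or when no
#'   2-consecutive-frame run exists), \code{auc}.
#' @examples
#' g <- genTraces(nCells = 10, responderFrac = 0.5, nPre = 20, nPost = 60,
#'                amplitude = 0.5, seed = 1)
#' head(analyzeTraces(g$traces))
#' @export
analyzeTraces <- function(ts, kSigma = 3, frac = 0.25, minPeakFrac = 0.10,
                          aucWindow = "post") {
  v <- traceValues(ts)
  sf <- stimFrame(ts)
  dt <- frameInterval(ts)
  rows <- lapply(seq_len(ncol(v)), function(j) {
    tr <- v[, j]
    b <- baselineStats(tr, sf, kSigma)
    cls <- classifyResponder(tr, b, sf, frac)
    onset <- if (cls$responder) responseTime(tr, b, sf, dt) else NA_real_
    data.frame(cell = cellIds(ts)[j], mu = b@mu, sigma = b@sigma,
               threshold = b@threshold, respondingFrac = cls$frac,
               responder = cls$responder, onset_s = onset,
               auc = traceAUC(tr, b, sf, dt, minPeakFrac, aucWindow),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group summary of per-cell trace results
#'
#' Mean +/- SEM of the AUC over all cells and of the onset time over
#' responders only, plus responder counts, as reported in group-level
#' figures.
#'
#' @param results data.frame from \code{\link{analyzeTraces}}.
#' @return A list: \code{nCells}, \code{nResponders}, \code{responderFrac},
#'   \code{auc} (list mean/sem/n), \code{onset} (list mean/sem/n, or NULL
#'   with a warning when there are no responders with onsets).
#' @export
summarizeTraces <- function(results) {
  if (nrow(results) < 1) stop("need at least one cell")
  onsets <- results$onset_s[results$responder & !is.na(results$onset_s)]
  onset <- if (length(onsets) >= 1) meanSEM(onsets) else {
    warning("no responding cells with an onset; onset summary absent")
    NULL
  }
  list(nCells = nrow(results),
       nResponders = sum(results$responder),
       responderFrac = mean(results$responder),
       auc = meanSEM(results$auc),
       onset = onset)
}
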