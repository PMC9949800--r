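#' Generate synthetic ratiometric calcium traces with known ground truth
#'
#' Simulates a cohort of single-cell ratiometric fluorescence traces: every
#' cell has i.i.d. Gaussian baseline noise around \code{baselineMu}; a fixed
#' fraction of cells ("responders") additionally receive a calcium transient
#' after the stimulus. The transient follows the double-exponential
#' \deqn{y(t) = A \, (1 - e^{-(t - t_0)/\tau_r}) \, e^{-(t - t_0)/\tau_d}}
#' for \eqn{t \ge t_0}, normalised so that its peak equals \code{amplitude}
#' exactly; the latency \eqn{t_0} (seconds after stimulus) is drawn from a
#' normal distribution truncated at 0.
#'
#' The number of responders is exactly \code{round(nCells * responderFrac)};
#' which cells respond is randomised. Identical arguments and seed give
#' bit-identical output.
#'
#' @param nCells number of cells.
#' @param responderFrac fraction of responding cells in [0, 1].
#' @param nPre baseline frame count (default 100).
#' @param nPost post-stimulus frame count (default 300).
#' @param dt seconds per frame (default 4).
#' @param baselineMu,baselineSigma baseline ratio mean and SD (ratio units).
#' @param amplitude transient peak height (ratio units); e.g. pass
#'   \code{10 * baselineSigma} for a high-SNR cohort.
#' @param latencyMean,latencySd latency distribution (seconds), truncated
#'   at 0.
#' @param riseTau,decayTau transient rise and decay time constants (s).
#'   The defaults (2 s rise, 600 s decay) emulate the fast onset and
#'   sustained plateau of agonist-evoked calcium influx through a
#'   non-inactivating channel, which stays elevated across a ~20 min
#'   post-stimulus recording.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return A list with elements \code{traces} (a \linkS4class{TraceSet}) and
#'   \code{truth} (list: logical \code{responder}, numeric \code{latency}
#'   seconds, NA for non-responders, plus the generating parameters).
#' @examples
#' g <- genTraces(nCells = 20, responderFrac = 0.5, nPre = 20, nPost = 60,
#'                amplitude = 0.5, seed = 1)
#' sum(g$truth$responder)
#' @export
genTraces <- function(nCells, responderFrac, nPre = 100L, nPost = 300L,
                      dt = 4.0, baselineMu = 1.0, baselineSigma = 0.05,
                      amplitude = 10 * baselineSigma,
                      latencyMean = 40, latencySd = 10,
                      riseTau = 2, decayTau = 600, seed = 1L) {
  if (responderFrac < 0 || responderFrac > 1)
    stop("responderFrac must be in [0, 1]")
  if (nPre < 1L || nPost < 1L) stop("nPre and nPost must be >= 1")
  if (dt <= 0) stop("dt must be positive")
  if (baselineSigma < 0) stop("baselineSigma must be non-negative")
  if (riseTau <= 0 || decayTau <= 0) stop("riseTau and decayTau must be positive")

  set.seed(as.integer(seed))
  nFrames <- nPre + nPost
  values <- matrix(stats::rnorm(nFrames * nCells, baselineMu, baselineSigma),
                   nFrames, nCells)

  nResp <- round(nCells * responderFrac)
  responder <- rep(FALSE, nCells)
  if (nCells > 0 && nResp > 0)
    responder[sample.int(nCells, nResp)] <- TRUE

  latency <- rep(NA_real_, nCells)
  if (nResp > 0) {
    # truncated normal at 0 by resampling
    lat <- stats::rnorm(nResp, latencyMean, latencySd)
    while (any(lat < 0))
      lat[lat < 0] <- stats::rnorm(sum(lat < 0), latencyMean, latencySd)
    latency[responder] <- lat
  }

  tPost <- seq_len(nPost) * dt  # frame times, seconds after stimulus
  for (j in which(responder)) {
    values[nPre + seq_len(nPost), j] <- values[nPre + seq_len(nPost), j] +
      amplitude * transientShape(tPost - latency[j], riseTau, decayTau)
  }

  ts <- TraceSet(values, stimFrame = nPre + 1L, dt = dt)
  truth <- list(responder = responder, latency = latency,
                params = list(nCells = nCells, responderFrac = responderFrac,
                              nPre = nPre, nPost = nPost, dt = dt,
                              baselineMu = baselineMu,
                              baselineSigma = baselineSigma,
                              amplitude = amplitude,
                              latencyMean = latencyMean,
                              latencySd = latencySd,
                              riseTau = riseTau, decayTau = decayTau,
                              seed = as.integer(seed)))
  list(traces = ts, truth = truth)
}

# Unit-peak double-exponential transient; 0 for t < 0.
transientShape <- function(t, riseTau, decayTau) {
  tPeak <- riseTau * log1p(decayTau / riseTau)
  peak <- (1 - exp(-tPeak / riseTau)) * exp(-tPeak / decayTau)
  y <- ifelse(t >= 0,
              (1 - exp(-pmax(t, 0) / riseTau)) * exp(-pmax(t, 0) / decayTau),
              0)
  y / peak
}

#' Generate per-cell ephys group tables with known group means
#'
#' Draws per-cell current densities from Gaussian distributions with the
#' specified group means and SDs, the fixture for
#' \code{\link{deltaCurrent}}.
#'
#' @param specs data.frame with columns \code{label}, \code{mean},
#'   \code{sd}, \code{n} and optionally \code{voltage} (mV; default NA).
#' @param seed integer RNG seed.
#' @return A list: \code{groups}, a named list of \linkS4class{EphysGroup};
#'   \code{truth}, the spec table.
#' @examples
#' g <- genEphysGroups(data.frame(label = c("basal", "inhibited"),
#'                                mean = c(50.13, 13.8), sd = 0, n = 5), seed = 1)
#' mean(groupDensity(g$groups$basal))
#' @export
genEphysGroups <- function(specs, seed = 1L) {
  stopifnot(all(c("label", "mean", "sd", "n") %in% names(specs)))
  if (any(specs$n < 1)) stop("each group needs n >= 1")
  if (any(specs$sd < 0)) stop("sd must be non-negative")
  if (is.null(specs$voltage)) specs$voltage <- NA_real_
  set.seed(as.integer(seed))
  groups <- lapply(seq_len(nrow(specs)), function(i) {
    EphysGroup(specs$label[i], specs$voltage[i],
               density = stats::rnorm(specs$n[i], specs$mean[i], specs$sd[i]))
  })
  names(groups) <- specs$label
  list(groups = groups, truth = specs)
}
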