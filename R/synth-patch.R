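#' Generate a synthetic single-channel patch record
#'
#' Simulates a two-state (closed/open) telegraph process with exponentially
#' distributed dwell times, current levels 0 and \code{iU} pA, and additive
#' Gaussian recording noise — the fixture for
#' \code{\link{unitaryCurrent}}.
#'
#' \code{pOpen} is the stationary open probability; the mean closed dwell is
#' derived as \code{dwellOpenMs * (1 - pOpen) / pOpen}. \code{pOpen = 0}
#' gives a permanently closed (single-level) record and \code{pOpen = 1} a
#' permanently open one.
#'
#' @param iU unitary current (pA, non-zero; negative for inward current).
#' @param pOpen stationary open probability in [0, 1].
#' @param dwellOpenMs mean open dwell time (ms).
#' @param fs sampling rate (Hz, default 3000).
#' @param durationS record length (seconds).
#' @param noiseSigma recording noise SD (pA).
#' @param seed integer RNG seed.
#' @return A list: \code{trace} (data.frame \code{t_s}, \code{I_pA}),
#'   \code{truth} (list with \code{iU}, \code{pOpen}, \code{state} vector).
#' @examples
#' g <- genPatchTrace(iU = -8, noiseSigma = 0, durationS = 0.5, seed = 1)
#' sort(unique(g$trace$I_pA))
#' @export
genPatchTrace <- function(iU = -8, pOpen = 0.5, dwellOpenMs = 10,
                          fs = 3000, durationS = 5, noiseSigma = 0.5,
                          seed = 1L) {
  if (iU == 0) stop("unitary current iU must be non-zero")
  if (pOpen < 0 || pOpen > 1) stop("pOpen must be in [0, 1]")
  if (dwellOpenMs <= 0 || fs <= 0 || durationS <= 0)
    stop("dwellOpenMs, fs and durationS must be positive")
  set.seed(as.integer(seed))

  n <- round(fs * durationS)
  tS <- (seq_len(n) - 1L) / fs
  state <- integer(n)  # 0 closed, 1 open

  if (pOpen == 0) {
    # stays closed
  } else if (pOpen == 1) {
    state[] <- 1L
  } else {
    dwellClosedMs <- dwellOpenMs * (1 - pOpen) / pOpen
    cur <- as.integer(stats::runif(1) < pOpen)
    i <- 1L
    while (i <= n) {
      meanMs <- if (cur == 1L) dwellOpenMs else dwellClosedMs
      len <- max(1L, round(stats::rexp(1, rate = 1 / meanMs) * fs / 1000))
      j <- min(n, i + len - 1L)
      state[i:j] <- cur
      cur <- 1L - cur
      i <- j + 1L
    }
  }

  I <- state * iU
  if (noiseSigma > 0) I <- I + stats::rnorm(n, 0, noiseSigma)
  list(trace = data.frame(t_s = tS, I_pA = I),
       truth = list(iU = iU, pOpen = pOpen, dwellOpenMs = dwellOpenMs,
                    state = state, seed = as.integer(seed)))
}
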