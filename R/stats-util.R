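#' Robust outlier removal (ROUT-style, constant model)
#'
#' Univariate version of the robust-fit + false-discovery-rate outlier
#' procedure: the robust centre is the median; the robust scale (RSDR) is
#' the 68.27th percentile of the absolute residuals times the small-sample
#' correction n / (n - K) with K = 1 fitted parameter. Each residual gets a
#' two-tailed t p-value (df = n - K), and residuals are tested from the
#' most extreme inward with a Benjamini-Hochberg-style step at FDR Q,
#' stopping at the first non-rejection. Flagged points are reported, never
#' silently deleted; affine transforms of the data flag the same points.
#'
#' @param x numeric vector, n >= 3 (fewer values are all kept with a
#'   warning).
#' @param Q target false-discovery rate among flagged points (default 0.01,
#'   i.e. 1 percent).
#' @return A list: \code{kept} values, \code{flagged} values,
#'   \code{isOutlier} logical mask over \code{x}, \code{q} per-point BH
#'   adjusted p-values (NA when not tested), \code{Q}, \code{rsdr}.
#' @examples
#' routOutliers(c(0, 0.1, -0.1, 0.05, 100))$flagged  # 100
#' @export
routOutliers <- function(x, Q = 0.01) {
  n <- length(x)
  if (n < 3) {
    warning("fewer than 3 values; outlier test not performed, all kept")
    return(list(kept = x, flagged = numeric(0),
                isOutlier = rep(FALSE, n), q = rep(NA_real_, n), Q = Q,
                rsdr = NA_real_))
  }
  resid <- x - stats::median(x)
  K <- 1
  rsdr <- stats::quantile(abs(resid), 0.6827, names = FALSE, type = 7) *
    n / (n - K)
  isOut <- rep(FALSE, n)
  qvals <- rep(NA_real_, n)
  if (rsdr > 0) {
    tstat <- resid / rsdr
    p <- 2 * stats::pt(-abs(tstat), df = n - K)
    ord <- order(p)                       # most extreme first
    for (i in seq_len(n)) {
      j <- ord[i]
      qvals[j] <- p[j] * n / i            # BH adjustment at rank i
      if (p[j] <= Q * i / n) isOut[j] <- TRUE else break
    }
  } else {
    # zero robust scale: flag only points off the (constant) bulk
    isOut <- abs(resid) > 0
    if (all(isOut)) isOut[] <- FALSE
  }
  list(kept = x[!isOut], flagged = x[isOut], isOutlier = isOut,
       q = qvals, Q = Q, rsdr = rsdr)
}

#' Mean and standard error of the mean
#'
#' @param x numeric vector, n >= 1.
#' @return A list: \code{mean}, \code{sem} (sample SD / sqrt(n); NA when
#'   n = 1), \code{n}.
#' @examples
#' meanSEM(c(1, 2, 3))  # mean 2, sem 0.577
#' @export
meanSEM <- function(x) {
  if (length(x) < 1) stop("need at least one value")
  n <- length(x)
  list(mean = mean(x),
       sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' \eqn{\Delta Ct = Ct_{target} - Ct_{housekeeping}} per condition,
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{reference}}, and
#' fold change \eqn{2^{-\Delta\Delta Ct}} relative to the reference
#' condition (e.g. expression versus a housekeeping gene such as TBP, with
#' an undifferentiated-cell reference time point).
#'
#' @param ctTarget,ctHousekeeping sample-condition Ct values.
#' @param refCtTarget,refCtHousekeeping reference-condition Ct values.
#' @return A list: \code{dctSample}, \code{dctRef}, \code{ddct},
#'   \code{fold}.
#' @examples
#' ddct(20, 25, 28, 25)$fold  # 256
#' @export
ddct <- function(ctTarget, ctHousekeeping, refCtTarget, refCtHousekeeping) {
  vals <- c(ctTarget, ctHousekeeping, refCtTarget, refCtHousekeeping)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  dctSample <- ctTarget - ctHousekeeping
  dctRef <- refCtTarget - refCtHousekeeping
  dd <- dctSample - dctRef
  list(dctSample = dctSample, dctRef = dctRef, ddct = dd, fold = 2^(-dd))
}
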