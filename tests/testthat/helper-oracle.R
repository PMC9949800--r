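# Brute-force frame-by-frame reference for the calcium-trace statistics.
# Written independently of the package implementation: explicit loops,
# dense numerical integration for the positive-part areas.

oracleBaseline <- function(trace, stimFrame, kSigma = 3) {
  base <- trace[1:(stimFrame - 1)]
  n <- length(base)
  mu <- sum(base) / n
  sigma <- sqrt(sum((base - mu)^2) / (n - 1))
  list(mu = mu, sigma = sigma, threshold = mu + kSigma * sigma)
}

oracleResponder <- function(trace, stimFrame, kSigma = 3, frac = 0.25) {
  th <- oracleBaseline(trace, stimFrame, kSigma)$threshold
  hits <- 0
  total <- 0
  for (f in stimFrame:length(trace)) {
    total <- total + 1
    if (trace[f] > th) hits <- hits + 1
  }
  hits / total >= frac
}

oracleOnset <- function(trace, stimFrame, dt, kSigma = 3) {
  th <- oracleBaseline(trace, stimFrame, kSigma)$threshold
  for (f in stimFrame:(length(trace) - 1)) {
    if (trace[f] > th && trace[f + 1] > th)
      return((f - stimFrame + 1) * dt)
  }
  NA_real_
}

# Positive-part area of the piecewise-linear baseline-subtracted trace over
# the post-stimulus window, per maximal y>0 run, excluding runs whose peak
# is below minPeakFrac of the window's min-to-max range. Areas by dense
# Riemann sums on the linear interpolant (independent of the analytic
# crossing formulae in the implementation).
oracleAUC <- function(trace, stimFrame, dt, kSigma = 3, minPeakFrac = 0.1,
                      nSub = 4000) {
  mu <- oracleBaseline(trace, stimFrame, kSigma)$mu
  y <- trace[stimFrame:length(trace)] - mu
  n <- length(y)
  if (n == 0 || max(y) <= 0) return(0)
  rng <- max(y) - min(y)

  # label maximal positive runs
  runId <- integer(n)
  cur <- 0
  for (i in 1:n) {
    if (y[i] > 0) {
      if (i == 1 || y[i - 1] <= 0) cur <- cur + 1
      runId[i] <- cur
    }
  }
  total <- 0
  for (r in seq_len(cur)) {
    idx <- which(runId == r)
    if (max(y[idx]) < minPeakFrac * rng) next
    a <- max(1, min(idx) - 1)
    b <- min(n, max(idx) + 1)
    tGrid <- seq((a - 1) * dt, (b - 1) * dt, length.out = (b - a) * nSub + 1)
    yGrid <- approx((seq_len(n) - 1) * dt, y, xout = tGrid)$y
    yGrid[yGrid < 0] <- 0
    # exclude parts of the boundary panels that belong to a neighbouring run
    if (a < min(idx) && y[a] > 0) {
      # panel a..a+1 shared with previous run: keep only from the crossing
      cross <- (a - 1) * dt + dt * y[a] / (y[a] - y[a + 1])
      yGrid[tGrid < cross] <- 0
    }
    if (b > max(idx) && y[b] > 0) {
      cross <- (b - 2) * dt + dt * y[b - 1] / (y[b - 1] - y[b])
      yGrid[tGrid > cross] <- 0
    }
    h <- tGrid[2] - tGrid[1]
    total <- total + sum((yGrid[-1] + yGrid[-length(yGrid)]) / 2) * h
  }
  total
}

# random short traces for oracle-equivalence checks
randomTrace <- function(nFrames = sample(6:20, 1), stimFrame = NULL) {
  if (is.null(stimFrame)) stimFrame <- sample(3:(nFrames - 2), 1)
  trace <- rnorm(nFrames, 1, 0.3)
  if (runif(1) < 0.5) {
    k <- stimFrame:nFrames
    trace[k] <- trace[k] + runif(1, 0, 2) * rbinom(length(k), 1, runif(1))
  }
  list(trace = trace, stimFrame = stimFrame)
}

# wrap a ground-truth label matrix as a SegmentationResult (truth numbering)
labelTruthSeg <- function(labels) {
  n <- max(labels)
  cen <- t(vapply(seq_len(n), function(l) {
    w <- which(labels == l, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  new("SegmentationResult", labels = labels,
      areas = as.integer(tabulate(labels[labels > 0], n)),
      centroids = cen, minArea = 0)
}
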