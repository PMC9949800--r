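flatBaseline <- function(mu = 0, sigma = 0, k = 3)
  new("BaselineStats", mu = mu, sigma = sigma, threshold = mu + k * sigma,
      kSigma = k)

test_that("baseline statistics use the n-1 SD estimator and mean + 3 SD threshold", {
  b <- baselineStats(c(rep(1, 10), 5, 5), stimFrame = 11)
  expect_equal(b@mu, 1)
  expect_equal(b@sigma, 0)
  expect_equal(b@threshold, 1)

  b2 <- baselineStats(c(1, 2, 3, 4, 5, 9), stimFrame = 6)
  expect_equal(b2@mu, 3)
  expect_equal(b2@sigma, sqrt(2.5))
  expect_equal(b2@threshold, 3 + 3 * sqrt(2.5), tolerance = 1e-12)

  expect_error(baselineStats(c(1, 2, 3), stimFrame = 2), "baseline frames")
})

test_that("baseline estimates recover the generating parameters within sampling error", {
  errsMu <- errsSd <- numeric(50)
  for (s in 1:50) {
    g <- genTraces(nCells = 1, responderFrac = 0, nPre = 100, nPost = 1,
                   baselineMu = 2, baselineSigma = 0.1, seed = s)
    b <- baselineStats(traceValues(g$traces)[, 1], stimFrame = 101)
    errsMu[s] <- b@mu - 2
    errsSd[s] <- b@sigma - 0.1
  }
  # 3 standard errors of the mean / of the SD estimate at n = 100
  expect_lt(abs(mean(errsMu)), 3 * 0.1 / sqrt(100 * 50))
  expect_lt(max(abs(errsMu)), 4 * 0.1 / sqrt(100))
  expect_lt(max(abs(errsSd)), 4 * 0.1 / sqrt(2 * 99))
})

test_that("responder rule: strict threshold, inclusive 25% boundary over post-stimulus frames", {
  # flat trace at the baseline mean never responds
  b <- flatBaseline(mu = 1, sigma = 0.1)
  flat <- rep(1, 310)
  cls <- classifyResponder(flat, b, stimFrame = 11)
  expect_false(cls$responder)
  expect_false(any(cls$mask))

  # all post frames far above threshold
  hot <- c(rep(1, 10), rep(1 + 5 * 0.1, 300))
  cls2 <- classifyResponder(hot, b, stimFrame = 11)
  expect_true(cls2$responder)
  expect_true(all(cls2$mask))

  # exactly 25% of 300 post frames supra-threshold: boundary is inclusive
  tr <- c(rep(1, 10), rep(2, 75), rep(1, 225))
  cls3 <- classifyResponder(tr, b, stimFrame = 11)
  expect_equal(cls3$frac, 0.25)
  expect_true(cls3$responder)
  # one frame fewer: non-responder
  tr2 <- c(rep(1, 10), rep(2, 74), rep(1, 226))
  expect_false(classifyResponder(tr2, b, stimFrame = 11)$responder)
})

test_that("onset time: first of two consecutive supra-threshold frames, first post frame at dt", {
  b <- flatBaseline(mu = 0, sigma = 0.1)  # threshold 0.3
  # run starts at the 3rd post-stimulus frame -> 3 * dt = 12 s at dt = 4
  tr <- c(rep(0, 5), 0, 0, 1, 1, 1)
  expect_equal(responseTime(tr, b, stimFrame = 6, dt = 4), 12)
  # a single isolated supra-threshold frame does not count
  tr2 <- c(rep(0, 5), 0, 1, 0, 1, 0)
  expect_true(is.na(responseTime(tr2, b, stimFrame = 6, dt = 4)))
  # response on the very first post frame -> dt, not 0
  tr3 <- c(rep(0, 5), 1, 1, 0, 0, 0)
  expect_equal(responseTime(tr3, b, stimFrame = 6, dt = 4), 4)
})

test_that("AUC: rectangular pulse, baseline Y = 0, trapezoids with interpolated crossings", {
  b <- flatBaseline()
  # y = [0 x5, 2 x10, 0 x5] at dt = 1: nine interior panels of 2, two edge panels of 1
  y <- c(0, rep(0, 4), rep(2, 10), rep(0, 5))
  expect_equal(traceAUC(y, b, stimFrame = 2, dt = 1), 20)
  # identically zero trace
  expect_equal(traceAUC(rep(0, 50), b, stimFrame = 2, dt = 1), 0)
  # all-negative trace has zero area
  expect_equal(traceAUC(c(0, rep(-1, 20)), b, stimFrame = 2, dt = 1), 0)
})

test_that("AUC peak filter: peaks below 10% of the min-to-max range are excluded", {
  b <- flatBaseline()
  mkTrace <- function(h2) c(0, 0, 10, 10, 0, 0, h2, h2, 0)  # two plateaus
  # second peak at 9% of range 10: excluded; at 11%: included
  a9 <- traceAUC(mkTrace(0.9), b, stimFrame = 2, dt = 1)
  a11 <- traceAUC(mkTrace(1.1), b, stimFrame = 2, dt = 1)
  firstOnly <- traceAUC(c(0, 0, 10, 10, 0, 0, 0, 0, 0), b, stimFrame = 2, dt = 1)
  expect_equal(a9, firstOnly)
  expect_equal(a11, firstOnly + 2 * 1.1)  # plateau 1.1 x 1 frame + 2 edges
})

test_that("AUC is additive over kept peaks and covariant under positive scaling", {
  b <- flatBaseline()
  set.seed(42)
  for (rep in 1:20) {
    y <- c(0, round(rnorm(25, 0, 1), 2))
    total <- traceAUC(y, b, stimFrame = 2, dt = 0.5, minPeakFrac = 0)
    # additivity: area of each positive run alone sums to the total
    runs <- rle(y[-1] > 0)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    pieces <- 0
    for (i in which(runs$values)) {
      yi <- rep(0, length(y) - 1)
      yi[starts[i]:ends[i]] <- y[-1][starts[i]:ends[i]]
      # neighbouring negative frames shape the crossings
      if (starts[i] > 1) yi[starts[i] - 1] <- min(y[-1][starts[i] - 1], 0)
      if (ends[i] < length(yi)) yi[ends[i] + 1] <- min(y[-1][ends[i] + 1], 0)
      pieces <- pieces + traceAUC(c(0, yi), b, 2, 0.5, minPeakFrac = 0)
    }
    expect_equal(total, pieces, tolerance = 1e-12)
    # scale covariance (minPeakFrac ratio-based, threshold fixed at 0)
    c3 <- traceAUC(c(0, 3 * y[-1]), b, 2, 0.5, minPeakFrac = 0.1)
    expect_equal(c3, 3 * traceAUC(y, b, 2, 0.5, minPeakFrac = 0.1),
                 tolerance = 1e-12)
  }
})

test_that("responder, onset and AUC agree with the brute-force reference on short random traces", {
  set.seed(7)
  for (i in 1:300) {
    rt <- randomTrace()
    tr <- rt$trace; sf <- rt$stimFrame
    b <- baselineStats(tr, sf)
    cls <- classifyResponder(tr, b, sf)
    expect_identical(cls$responder, oracleResponder(tr, sf))
    expect_equal(responseTime(tr, b, sf, dt = 2), oracleOnset(tr, sf, dt = 2))
    expect_equal(traceAUC(tr, b, sf, dt = 2), oracleAUC(tr, sf, dt = 2),
                 tolerance = 1e-5)
  }
})

test_that("raising the transient amplitude never demotes a responder (fixed threshold)", {
  g <- genTraces(nCells = 40, responderFrac = 0.5, nPre = 30, nPost = 90,
                 amplitude = 0.2, seed = 3)
  v <- traceValues(g$traces)
  for (j in seq_len(ncol(v))) {
    b <- baselineStats(v[, j], 31)
    r1 <- classifyResponder(v[, j], b, 31)$responder
    # add extra transient on top (amplitude increase), threshold unchanged
    boosted <- v[, j]
    boosted[31:120] <- boosted[31:120] + 0.3
    r2 <- classifyResponder(boosted, b, 31)$responder
    expect_false(r1 && !r2)
  }
})

test_that("cohort analysis recovers the programmed responder fraction at high SNR", {
  g <- genTraces(nCells = 200, responderFrac = 0.6, amplitude = 10 * 0.05,
                 baselineSigma = 0.05, seed = 1)
  res <- analyzeTraces(g$traces)
  expect_lt(abs(mean(res$responder) - 0.6), 0.05)
  # classification matches the ground-truth mask almost everywhere
  expect_gt(mean(res$responder == g$truth$responder), 0.95)
})

test_that("group summaries: mean +/- SEM, onset over responders only, zero-responder flagging", {
  res <- data.frame(cell = c("a", "b", "c"), mu = 1, sigma = 0, threshold = 1,
                    respondingFrac = c(1, 1, 0), responder = c(TRUE, TRUE, FALSE),
                    onset_s = c(12, 12, NA), auc = c(1, 2, 3))
  s <- summarizeTraces(res)
  expect_equal(s$nResponders, 2)
  expect_equal(s$onset$mean, 12)
  expect_equal(s$onset$sem, 0)
  expect_equal(s$auc$mean, 2)
  expect_equal(s$auc$sem, 1 / sqrt(3), tolerance = 1e-12)

  res0 <- res; res0$responder <- FALSE; res0$onset_s <- NA
  expect_warning(s0 <- summarizeTraces(res0), "onset")
  expect_null(s0$onset)
})
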