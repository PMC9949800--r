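mkPair <- function(green, red) {
  ImageStackPair(array(green, c(dim(green), 1)), array(red, c(dim(red), 1)))
}

test_that("ratio stack divides filtered green by red and masks invalid pixels", {
  red <- matrix(100, 32, 32)
  pair <- mkPair(2 * red, red)
  r <- ratioStack(pair)
  expect_equal(max(abs(r - 2)), 0, tolerance = 1e-4)

  # single-pixel impulse removed by the 3x3 median
  g2 <- matrix(100, 32, 32); g2[16, 16] <- 10000
  r2 <- ratioStack(mkPair(g2, red))
  expect_equal(r2[16, 16, 1], 1, tolerance = 1e-3)

  # zero-red pixels are masked NA, not clamped
  red3 <- matrix(100, 32, 32); red3[1:8, 1:8] <- 0
  r3 <- ratioStack(mkPair(matrix(100, 32, 32), red3), medianRadius = 0)
  expect_true(all(is.na(r3[1:8, 1:8, 1])))
  expect_true(all(is.finite(r3[20:32, 20:32, 1])))

  # an all-zero red frame warns and is fully masked
  expect_warning(ratioStack(mkPair(matrix(1, 8, 8), matrix(0, 8, 8)),
                            medianRadius = 0),
                 "masked")
})

test_that("round trip: in-cell ratio traces track the generating trace within 2%", {
  g <- genImageStack(nCells = 3, shape = c(96, 96), radii = 10,
                     redIntensity = 1000, noiseSigma = 10,  # 1% of red level
                     traceArgs = list(responderFrac = 1, nPre = 5, nPost = 15,
                                      amplitude = 0.5), seed = 6)
  r <- ratioStack(g$stack)
  truthTr <- traceValues(g$truth$traces)
  for (lab in 1:3) {
    inCell <- g$truth$labels == lab
    meas <- apply(r, 3, function(fr) mean(fr[inCell], na.rm = TRUE))
    expect_lt(max(abs(meas - truthTr[, lab]) / truthTr[, lab]), 0.02)
  }
})

test_that("segmentation: blank image gives zero labels, a valid empty result", {
  blank <- array(0, c(32, 32, 2))
  seg <- segmentCells(blank)
  expect_length(labelAreas(seg), 0)
  expect_true(all(labelImage(seg) == 0))
})

test_that("five well-separated disks segment into five labels with near-disk areas", {
  g <- genImageStack(nCells = 5, shape = c(128, 128), radii = 10,
                     traceArgs = list(responderFrac = 0, nPre = 3, nPost = 3),
                     seed = 4)
  seg <- segmentCells(g$stack, minArea = 100)
  expect_length(labelAreas(seg), 5)
  expect_true(all(abs(labelAreas(seg) - pi * 100) <= 40))
  # labels ordered by decreasing area
  expect_true(all(diff(labelAreas(seg)) <= 0))
})

test_that("watershed splits two overlapping disks (centres 1.5 radii apart) into two labels", {
  g <- genImageStack(centers = rbind(c(40, 32), c(40, 47)), radii = 10,
                     shape = c(80, 80),
                     traceArgs = list(responderFrac = 0, nPre = 3, nPost = 3),
                     seed = 1)
  expect_equal(nrow(g$truth$touching), 1)  # generator flags the pair
  seg <- segmentCells(g$stack, minArea = 50)
  expect_length(labelAreas(seg), 2)
})

test_that("label count is non-increasing in the minimum-area filter", {
  g <- genImageStack(nCells = 6, shape = c(128, 128), radii = c(5, 5, 8, 8, 12, 12),
                     traceArgs = list(responderFrac = 0, nPre = 3, nPost = 3),
                     seed = 9)
  counts <- vapply(c(0, 50, 100, 200, 500),
                   function(a) length(labelAreas(segmentCells(g$stack, minArea = a))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Otsu segmentation is invariant to a global affine rescaling of the red channel", {
  g <- genImageStack(nCells = 4, shape = c(96, 96), radii = 9, noiseSigma = 0,
                     traceArgs = list(responderFrac = 0, nPre = 3, nPost = 3),
                     seed = 5)
  seg1 <- segmentCells(g$stack, minArea = 50)
  scaled <- ImageStackPair(g$stack@green, g$stack@red * 3.7 + 20)
  seg2 <- segmentCells(scaled, minArea = 50)
  expect_identical(labelImage(seg1), labelImage(seg2))
})

test_that("trace extraction averages valid pixels and drops fully invalid cells", {
  labs <- matrix(0L, 4, 4)
  labs[1, 1:4] <- 1L
  seg <- new("SegmentationResult", labels = labs, areas = 4L,
             centroids = matrix(c(1, 2.5), 1, 2), minArea = 1)
  ratio <- array(NA_real_, c(4, 4, 3))
  for (t in 1:3) ratio[1, , t] <- c(1, 2, 3, 4)
  ratio[2:4, , ] <- 2
  ts <- extractTraces(ratio, seg, stimFrame = 2, dt = 1)
  expect_equal(unname(traceValues(ts)[, 1]), rep(2.5, 3))

  # uniform ratio gives a constant trace for any mask
  ratio2 <- array(2, c(4, 4, 3))
  expect_equal(unname(traceValues(extractTraces(ratio2, seg, 2, 1))[, 1]),
               rep(2, 3))

  # a cell fully invalid in one frame is dropped with a warning
  labs2 <- labs; labs2[3, 1:4] <- 2L
  seg2 <- new("SegmentationResult", labels = labs2, areas = c(4L, 4L),
              centroids = rbind(c(1, 2.5), c(3, 2.5)), minArea = 1)
  ratio3 <- ratio
  ratio3[3, , 2] <- NA_real_
  expect_warning(ts2 <- extractTraces(ratio3, seg2, 2, 1), "dropping")
  expect_equal(nCells(ts2), 1)
})

test_that("extracted traces correlate > 0.99 with the generating trace at 1% noise", {
  g <- genImageStack(nCells = 4, shape = c(96, 96), radii = 9,
                     redIntensity = 1000, noiseSigma = 10,
                     traceArgs = list(responderFrac = 1, nPre = 10, nPost = 30,
                                      amplitude = 0.5), seed = 8)
  r <- ratioStack(g$stack)
  ts <- extractTraces(r, labelTruthSeg(g$truth$labels), 11, 4)
  truthTr <- traceValues(g$truth$traces)
  for (j in 1:4)
    expect_gt(cor(traceValues(ts)[, j], truthTr[, j]), 0.99)
})
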