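test_that("contact point is recovered to 1e-4 um on a noiseless rigid-cantilever curve", {
  g <- genForceCurve(E = 15, z0 = 1, k = 1e9, noiseSigma = 0, seed = 1)
  expect_lt(abs(findContactPoint(g$curve) - 1), 1e-4)
  # compliant cantilever: deflection-corrected linearisation still exact
  g2 <- genForceCurve(E = 15, z0 = 1, k = 7.83, noiseSigma = 0, seed = 1)
  expect_lt(abs(findContactPoint(g2$curve) - 1), 1e-4)
})

test_that("a curve that never contacts the sample is a reported fit failure", {
  set.seed(1)
  z <- seq(0, 3, length.out = 300)
  flat <- ForceCurve(z, rnorm(300, 0, 0.2), k = 7.83, R = 2.5)
  expect_error(findContactPoint(flat), class = "calcimech_fit_error")
})

test_that("contact point is within 0.02 um of truth in >= 90% of noisy replicates", {
  hits <- vapply(1:50, function(s) {
    g <- genForceCurve(E = 15, z0 = 1, noiseSigma = 1, seed = s)
    abs(findContactPoint(g$curve) - 1) < 0.02
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Hertz fit recovers the modulus exactly on noiseless curves, and scales linearly in force", {
  g <- genForceCurve(E = 15, z0 = 1, noiseSigma = 0, seed = 1)
  fit <- fitHertz(g$curve, findContactPoint(g$curve))
  expect_lt(abs(modulus(fit) - 15) / 15, 0.001)

  # doubling all forces (same indentation) doubles E: scale deflection and k
  # so F = k*d doubles while the deflection correction d/1000 is unchanged
  c2 <- ForceCurve(g$curve@z, g$curve@deflection, k = 2 * g$curve@k,
                   R = 2.5, nu = 0.5)
  # note: delta = (z - z0) - d/1000 uses d in nm, unchanged here
  fit2 <- fitHertz(c2, contactPoint(fit))
  expect_equal(modulus(fit2), 2 * modulus(fit), tolerance = 1e-9)
})

test_that("dimensional contract: F in nN and delta, R in um give E in kPa", {
  # single-point closed form: F = 1 nN at delta = 1 um, R = 2.5 um, nu = 0.5
  # E = 3 (1 - nu^2) / (4 sqrt(R)) = 0.3558 kPa
  k <- 1e9  # rigid: deflection correction negligible
  z <- seq(0, 2, length.out = 2001)
  F <- (4 / 3) * (1 / (1 - 0.25)) * sqrt(2.5) * 0.3558 * pmax(z, 0)^1.5
  crv <- ForceCurve(z, F / k, k = k, R = 2.5, nu = 0.5)
  fit <- fitHertz(crv, 0)
  expect_equal(modulus(fit), 0.3558, tolerance = 1e-6)
  expect_equal(3 * (1 - 0.25) / (4 * sqrt(2.5)), 0.35576, tolerance = 1e-4)
})

test_that("unit invariance: converting to SI and back leaves E unchanged to 1e-9 relative", {
  g <- genForceCurve(E = 12, z0 = 0.8, noiseSigma = 0.5, seed = 2)
  crv <- g$curve
  si <- ForceCurve(crv@z * 1 , crv@deflection * 1, k = crv@k, R = crv@R,
                   nu = crv@nu)  # round trip through metres and newtons
  zm <- crv@z * 1e-6; dm <- crv@deflection * 1e-9
  back <- ForceCurve(zm * 1e6, dm * 1e9, k = crv@k, R = crv@R, nu = crv@nu)
  z0 <- findContactPoint(crv)
  e1 <- modulus(fitHertz(crv, z0))
  e2 <- modulus(fitHertz(back, z0))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("the rigid-cantilever limit of the corrected fit equals the uncorrected fit", {
  g <- genForceCurve(E = 15, z0 = 1, k = 1e12, noiseSigma = 0, seed = 1)
  z0 <- findContactPoint(g$curve)
  fit <- fitHertz(g$curve, z0)
  # uncorrected: treat deflection as zero (pure z - z0 indentation)
  un <- ForceCurve(g$curve@z, g$curve@deflection, k = g$curve@k, R = 2.5)
  F <- force(un)
  delta <- pmax(un@z - z0, 1e-12)
  sel <- F >= 0.1 * max(F) & F <= 0.9 * max(F)
  Cun <- sum(F[sel] * delta[sel]^1.5) / sum(delta[sel]^3)
  Eun <- 3 * Cun * (1 - 0.25) / (4 * sqrt(2.5))
  expect_equal(modulus(fit), Eun, tolerance = 1e-6)
})

test_that("modulus recovery across the physiological range: bias < 1%, SD < 5% at 1 nN noise", {
  for (E in c(10, 15, 20)) {
    Ehat <- vapply(1:50, function(s) {
      g <- genForceCurve(E = E, z0 = 1, noiseSigma = 1, seed = s)
      modulus(fitHertz(g$curve, findContactPoint(g$curve)))
    }, numeric(1))
    expect_lt(abs(mean(Ehat) - E) / E, 0.01)
    expect_lt(sd(Ehat) / E, 0.05)
  }
})

test_that("assumed Poisson's ratio rescales E by (1 - nu^2)", {
  g <- genForceCurve(E = 15, z0 = 1, noiseSigma = 0, seed = 1)
  z0 <- findContactPoint(g$curve)
  nus <- c(0, 0.2, 0.4, 0.5)
  Es <- vapply(nus, function(nu) {
    crv <- ForceCurve(g$curve@z, g$curve@deflection, k = g$curve@k, R = 2.5,
                      nu = nu)
    modulus(fitHertz(crv, z0))
  }, numeric(1))
  expect_equal(Es / Es[4], (1 - nus^2) / (1 - 0.5^2), tolerance = 1e-9)
})

test_that("indentation grids follow the floor(side/spacing) half-offset convention", {
  g <- makeGrid(10, 0.5)
  expect_equal(nrow(g), 400)
  expect_equal(nrow(makeGrid(1, 0.5)), 4)
  expect_equal(nrow(makeGrid(0.4, 0.5)), 1)  # spacing > side: centre point
  expect_equal(makeGrid(0.4, 0.5)$x, 0.2)
  expect_equal(sort(unique(g$x)), (1:20 - 0.5) * 0.5)
})

test_that("map analysis aggregates fits and accounts for failures explicitly", {
  curves <- lapply(1:10, function(s)
    genForceCurve(E = if (s <= 5) 10 else 20, z0 = 1, noiseSigma = 0.5,
                  seed = s)$curve)
  map <- analyzeMap(curves)
  expect_equal(map$summary$nFail, 0)
  expect_equal(map$summary$meanE, 15, tolerance = 0.02)
  expect_true(map$summary$medianE >= 9.5 && map$summary$medianE <= 20.5)

  # one unparseable curve among 10: 9 fits + 1 reported failure
  set.seed(3)
  curves[[4]] <- ForceCurve(seq(0, 3, length.out = 200),
                            rnorm(200, 0, 0.2), k = 7.83, R = 2.5)
  map2 <- analyzeMap(curves)
  expect_equal(map2$summary$nFail, 1)
  expect_equal(sum(map2$fits$status == "ok"), 9)
  expect_match(map2$fits$message[map2$fits$status == "failed"], "baseline")

  # every curve failing is an error with diagnostics
  allBad <- lapply(1:3, function(i) {
    set.seed(i)
    ForceCurve(seq(0, 3, length.out = 200), rnorm(200, 0, 0.2),
               k = 7.83, R = 2.5)
  })
  expect_error(analyzeMap(allBad), "all 3 fits failed")
})
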