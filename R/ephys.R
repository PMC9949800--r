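#' Whole-cell current density
#'
#' Normalises whole-cell current by membrane capacitance so cells of
#' different sizes are comparable.
#'
#' @param I_pA current(s) in pA.
#' @param C_pF membrane capacitance(s) in pF, strictly positive.
#' @return Current density in pA/pF (elementwise \code{I_pA / C_pF}).
#' @examples
#' currentDensity(100, 10)  # 10 pA/pF
#' @export
currentDensity <- function(I_pA, C_pF) {
  if (any(!is.finite(C_pF)) || any(C_pF <= 0))
    stop("capacitance must be positive and finite (pF)")
  I_pA / C_pF
}

#' Basal-minus-inhibited current difference (channel-specific current)
#'
#' Isolates the current through the channel of interest as the difference
#' between each cell's basal current density (no antagonist) and the
#' average current density of the antagonist-inhibited group:
#' \eqn{\Delta_i = \mathrm{basal}_i - \overline{\mathrm{inhibited}}}. The
#' group mean of the deltas therefore equals mean(basal) - mean(inhibited)
#' exactly. The SEM is computed over the basal cells, the inhibited-group
#' mean being treated as a constant reference.
#'
#' @param basal an \linkS4class{EphysGroup}, recordings without antagonist.
#' @param inhibited an \linkS4class{EphysGroup}, recordings with the
#'   channel blocked; must be at the same holding potential (labels are
#'   not required to match, as the two groups differ by condition).
#' @return A list: \code{delta} per-cell deltas (pA/pF), \code{mean},
#'   \code{sem}, \code{n} (basal group size), \code{inhibitedMean}.
#' @examples
#' b <- EphysGroup("T89I:basal", -70, density = c(60, 40.26))  # mean 50.13
#' i <- EphysGroup("T89I:GSK205", -70, density = c(10, 17.6))  # mean 13.8
#' deltaCurrent(b, i)$mean                                     # 36.33
#' @export
deltaCurrent <- function(basal, inhibited) {
  if (!isTRUE(all.equal(holdingPotential(basal), holdingPotential(inhibited))) &&
      !(is.na(holdingPotential(basal)) && is.na(holdingPotential(inhibited))))
    stop(sprintf(
      "holding potentials differ (%g vs %g mV); refusing to compare groups",
      holdingPotential(basal), holdingPotential(inhibited)))
  ref <- mean(groupDensity(inhibited))
  delta <- groupDensity(basal) - ref
  s <- meanSEM(delta)
  list(delta = delta, mean = s$mean, sem = s$sem, n = s$n,
       inhibitedMean = ref)
}

#' Unitary current from a single-channel record
#'
#' Estimates the single-channel current step from the all-points amplitude
#' histogram: a two-component Gaussian mixture (closed and open levels) is
#' fitted to the sample amplitudes by EM (k-means initialisation, several
#' restarts, best likelihood kept) and the unitary current is the distance
#' between the component means, \eqn{i_u = |\mu_{open} - \mu_{closed}|},
#' reported as a magnitude. The estimate is invariant to any constant
#' offset on the trace.
#'
#' @param I_pA numeric vector of sampled currents (pA), length >= 1000.
#' @param minWeight mixtures whose minor component carries less weight than
#'   this are considered single-level (default 0.01).
#' @param nRestarts number of k-means/EM restarts (default 10).
#' @param seed RNG seed for the restarts (default 1).
#' @return A list: \code{iU} (pA magnitude, NA when no second level),
#'   \code{status} ("ok" or "no second level detected"), \code{mu}
#'   (component means, closed first), \code{sigma}, \code{weight},
#'   \code{logLik}.
#' @examples
#' g <- genPatchTrace(iU = -8, noiseSigma = 0.5, durationS = 2, seed = 1)
#' unitaryCurrent(g$trace$I_pA)$iU
#' @export
unitaryCurrent <- function(I_pA, minWeight = 0.01, nRestarts = 10L,
                           seed = 1L) {
  if (length(I_pA) < 1000)
    stop("need at least 1000 samples for an amplitude histogram")
  x <- as.numeric(I_pA)
  noSecond <- list(iU = NA_real_, status = "no second level detected",
                   mu = rep(mean(x), 2), sigma = c(stats::sd(x), NA),
                   weight = c(1, 0), logLik = NA_real_)
  rng <- diff(range(x))
  if (rng == 0) return(noSecond)

  # noiseless records: <= 2 distinct support points need no EM
  ux <- unique(x)
  if (length(ux) == 2) {
    w <- mean(x == max(ux))
    if (min(w, 1 - w) < minWeight) return(noSecond)
    mu <- ux[order(abs(ux))]   # closed (near 0) first
    return(list(iU = abs(diff(sort(ux))), status = "ok", mu = mu,
                sigma = c(0, 0),
                weight = c(mean(x == mu[1]), mean(x == mu[2])),
                logLik = Inf))
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    km <- tryCatch(stats::kmeans(x, centers = 2, nstart = 1),
                   error = function(e) NULL)
    if (is.null(km)) next
    fit <- gmm2EM(x, km)
    if (!is.null(fit) && (is.null(best) || fit$logLik > best$logLik))
      best <- fit
  }
  if (is.null(best)) return(noSecond)
  ord <- order(abs(best$mu))   # closed level is the one nearer 0
  best$mu <- best$mu[ord]; best$sigma <- best$sigma[ord]
  best$weight <- best$weight[ord]
  if (min(best$weight) < minWeight ||
      abs(diff(best$mu)) < 1e-6 * rng) return(noSecond)
  list(iU = abs(diff(best$mu)), status = "ok", mu = best$mu,
       sigma = best$sigma, weight = best$weight, logLik = best$logLik)
}

# Two-component univariate Gaussian mixture by EM from a k-means start.
gmm2EM <- function(x, km, maxIter = 500L, tol = 1e-8) {
  n <- length(x)
  mu <- as.numeric(km$centers)
  sdFloor <- 1e-6 * diff(range(x))
  sig <- pmax(sqrt(km$withinss / pmax(km$size, 1)), sdFloor)
  w <- km$size / n
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sig[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    newLL <- sum(log(tot))
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-9 || n2 < 1e-9) return(NULL)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sig <- pmax(c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
                  sqrt(sum((1 - g1) * (x - mu[2])^2) / n2)), sdFloor)
    w <- c(n1, n2) / n
    if (is.finite(ll) && abs(newLL - ll) < tol) break
    ll <- newLL
  }
  list(mu = mu, sigma = sig, weight = w, logLik = newLL)
}
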