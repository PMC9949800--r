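#' Generate a synthetic AFM force curve with known modulus and contact point
#'
#' Builds an approach curve for a spherical indenter on an elastic
#' half-space. Before contact (\eqn{z < z_0}) the force is zero plus noise;
#' after contact it follows the Hertz relation
#' \deqn{F = \frac{4}{3} \frac{E}{1 - \nu^2} \sqrt{R} \, \delta^{3/2},
#'   \qquad \delta = (z - z_0) - d,}
#' where the cantilever deflection \eqn{d = F / k} couples force and
#' indentation. The implicit equation is solved per point by fixed-point
#' iteration (tolerance 1e-6 nN, at most 100 iterations). The curve is
#' truncated at \code{Fmax}.
#'
#' Unit contract: forces in nN, lengths in micrometres, E in kPa, k in N/m
#' (so the deflection F/k comes out in nm).
#'
#' @param E elastic modulus (kPa).
#' @param z0 contact point (micrometres).
#' @param R tip radius (micrometres, default 2.5 = 5 um diameter sphere).
#' @param nu Poisson's ratio (default 0.5).
#' @param k spring constant (N/m, default 7.83).
#' @param Fmax maximum force (nN, default 300).
#' @param nPoints number of samples along z (default 500).
#' @param preContact length of the pre-contact baseline (micrometres,
#'   default 1).
#' @param noiseSigma additive force noise SD (nN, default 0). Noise is
#'   applied to the deflection signal as noiseSigma / k.
#' @param seed integer RNG seed.
#' @return A list: \code{curve} (\linkS4class{ForceCurve}) and \code{truth}
#'   (list with \code{E}, \code{z0} and the generating parameters).
#' @examples
#' g <- genForceCurve(E = 15, z0 = 1, noiseSigma = 0, seed = 1)
#' max(force(g$curve))
#' @export
genForceCurve <- function(E, z0 = 1, R = 2.5, nu = 0.5, k = 7.83,
                          Fmax = 300, nPoints = 500L, preContact = 1,
                          noiseSigma = 0, seed = 1L) {
  if (E <= 0 || R <= 0 || k <= 0 || Fmax <= 0)
    stop("E, R, k and Fmax must be positive")
  if (nu < 0 || nu > 0.5) stop("nu must be in [0, 0.5]")
  set.seed(as.integer(seed))

  C <- hertzPrefactor(E, R, nu)               # nN / um^(3/2)
  deltaMax <- (Fmax / C)^(2 / 3)              # um
  zMax <- z0 + deltaMax + Fmax / (1000 * k)   # add deflection in um
  z <- seq(z0 - preContact, zMax, length.out = nPoints)

  F <- vapply(z, function(zi) hertzForceAtZ(zi, z0, C, k), numeric(1))
  deflection <- F / k                          # nm
  if (noiseSigma > 0)
    deflection <- deflection + stats::rnorm(nPoints, 0, noiseSigma / k)

  curve <- ForceCurve(z, deflection, k = k, R = R, nu = nu)
  list(curve = curve,
       truth = list(E = E, z0 = z0, R = R, nu = nu, k = k, Fmax = Fmax,
                    noiseSigma = noiseSigma, seed = as.integer(seed)))
}

# F = C * ((z - z0) - F/(1000 k))^{3/2}, solved by fixed point.
# z in um, F in nN, k in N/m (F/k is nm, /1000 -> um).
hertzForceAtZ <- function(z, z0, C, k, tol = 1e-6, maxIter = 100L) {
  if (z <= z0) return(0)
  F <- C * (z - z0)^1.5
  for (i in seq_len(maxIter)) {
    delta <- (z - z0) - F / (1000 * k)
    Fnew <- if (delta > 0) C * delta^1.5 else 0
    if (abs(Fnew - F) < tol) return(Fnew)
    F <- Fnew
  }
  stop(sprintf(
    "deflection-corrected Hertz force did not converge at z = %.4g um (last step %.3g nN)",
    z, abs(Fnew - F)))
}

# Hertz prefactor C = (4/3) E sqrt(R) / (1 - nu^2); E kPa, R um -> C nN/um^1.5
hertzPrefactor <- function(E, R, nu) (4 / 3) * E * sqrt(R) / (1 - nu^2)
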