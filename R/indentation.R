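#' Contact-point extrapolation for a spherical-indenter force curve
#'
#' For Hertzian spherical contact, \eqn{F^{2/3}} is linear in the
#' tip-sample separation, so regressing \eqn{F^{2/3}} on the
#' deflection-corrected piezo position \eqn{z - d} over a mid-force window
#' and extrapolating to zero force gives the contact point \eqn{z_0} as the
#' regression line's intercept with the abscissa. The window is re-selected
#' once relative to the first estimate and the regression repeated.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param fLo,fHi force window as fractions of the maximum force (defaults
#'   0.10 and 0.90, avoiding baseline noise and deep-indentation
#'   nonlinearity).
#' @param minSNR minimum ratio of peak force to pre-contact RMS noise; the
#'   curve must reach at least \code{minSNR} times the baseline RMS
#'   (default 10), else the probe never meaningfully contacted the sample.
#' @return Contact point z0 in micrometres. Signals an error of class
#'   \code{calcimech_fit_error} when no window points exist, the slope is
#'   not positive, or the curve never leaves the baseline.
#' @examples
#' g <- genForceCurve(E = 15, z0 = 1, noiseSigma = 0)
#' findContactPoint(g$curve)
#' @export
findContactPoint <- function(curve, fLo = 0.10, fHi = 0.90, minSNR = 10) {
  F <- force(curve)
  zEff <- curve@z - curve@deflection / 1000   # deflection-corrected, um
  Fmax <- max(F)

  baseRMS <- stats::sd(F[seq_len(max(2L, floor(length(F) * 0.1)))])
  if (is.finite(baseRMS) && baseRMS > 0 && Fmax < minSNR * baseRMS)
    fitError("curve never leaves the baseline (max force %.3g nN < %g x baseline RMS %.3g nN)",
             Fmax, minSNR, baseRMS)
  if (Fmax <= 0)
    fitError("curve has no positive force; nothing to fit")

  z0 <- linearizedIntercept(zEff, F, fLo * Fmax, fHi * Fmax)
  # one refinement pass: same force window, restricted to z past z0
  sel <- zEff > z0
  z0 <- linearizedIntercept(zEff[sel], F[sel], fLo * Fmax, fHi * Fmax)
  z0
}

# Regress F^(2/3) on z over points with F in [lo, hi]; return the z-intercept.
linearizedIntercept <- function(z, F, lo, hi) {
  sel <- F >= lo & F <= hi
  if (sum(sel) < 2)
    fitError("fewer than 2 points in the force window [%.3g, %.3g] nN", lo, hi)
  fit <- stats::lm.fit(cbind(1, z[sel]), F[sel]^(2 / 3))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope <= 0)
    fitError("non-positive linearized slope (%.3g); curve is not Hertzian over the window",
             slope)
  unname(-fit$coefficients[1] / slope)
}

fitError <- function(fmt, ...) {
  stop(structure(class = c("calcimech_fit_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Fit the spherical-indenter Hertz model to a force curve
#'
#' Least-squares fit of \eqn{F = C \, \delta^{3/2}} with
#' \eqn{C = (4/3) E \sqrt{R} / (1 - \nu^2)} over a mid-force window, using
#' the deflection-corrected indentation \eqn{\delta = (z - z_0) - d} (d =
#' cantilever deflection; the "modified" Hertz analysis). With \eqn{z_0}
#' fixed the model is linear in C, so the least-squares minimiser is the
#' closed form \eqn{C = \sum F \delta^{3/2} / \sum \delta^3}.
#'
#' Unit contract: F in nN, z / \eqn{\delta} / R in micrometres, deflection
#' in nm, k in N/m; then E comes out in kPa.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param z0 contact point (micrometres), from
#'   \code{\link{findContactPoint}} or user-supplied.
#' @param window force-fraction window c(lo, hi) of the maximum force over
#'   which to fit (default c(0.10, 0.90)).
#' @return A \linkS4class{HertzFit}. Signals \code{calcimech_fit_error}
#'   when no window point has positive indentation.
#' @examples
#' g <- genForceCurve(E = 15, z0 = 1, noiseSigma = 0)
#' fitHertz(g$curve, findContactPoint(g$curve))
#' @export
fitHertz <- function(curve, z0, window = c(0.10, 0.90)) {
  F <- force(curve)
  delta <- (curve@z - z0) - curve@deflection / 1000
  Fmax <- max(F)
  sel <- F >= window[1] * Fmax & F <= window[2] * Fmax & delta > 0
  if (sum(sel) < 1)
    fitError("no points with positive indentation in the %g-%g%% force window",
             100 * window[1], 100 * window[2])
  d32 <- delta[sel]^1.5
  C <- sum(F[sel] * d32) / sum(d32^2)
  E <- 3 * C * (1 - curve@nu^2) / (4 * sqrt(curve@R))
  if (!is.finite(E) || E <= 0)
    fitError("non-physical modulus estimate (%.3g kPa)", E)
  rms <- sqrt(mean((F[sel] - C * d32)^2))
  new("HertzFit", z0 = z0, E = E, window = as.numeric(window), rms = rms,
      nPoints = as.integer(sum(sel)))
}

#' Square indentation grid
#'
#' Lattice of indentation sites over a square region: floor(side / spacing)
#' points per axis at half-spacing offsets, so a 10 um side at 0.5 um
#' spacing gives 20 x 20 = 400 sites. Spacing larger than the side
#' degenerates to the single centre point.
#'
#' @param side region side length (micrometres).
#' @param spacing lattice interval (micrometres).
#' @return data.frame with columns \code{x}, \code{y} (micrometres).
#' @examples
#' nrow(makeGrid(10, 0.5))  # 400
#' @export
makeGrid <- function(side = 10, spacing = 0.5) {
  if (side <= 0 || spacing <= 0) stop("side and spacing must be positive")
  nAxis <- floor(side / spacing)
  if (nAxis < 1) return(data.frame(x = side / 2, y = side / 2))
  offs <- (seq_len(nAxis) - 0.5) * spacing
  g <- expand.grid(x = offs, y = offs)
  g[order(g$y, g$x), c("x", "y"), drop = FALSE]
}

#' Analyse a map of force curves
#'
#' Runs \code{\link{findContactPoint}} + \code{\link{fitHertz}} on every
#' curve; fit failures are counted and reported per curve, never silently
#' dropped. Location summaries (mean and median modulus) are computed over
#' successful fits only.
#'
#' @param curves list of \linkS4class{ForceCurve} objects (optionally
#'   named); one per grid point.
#' @param coords optional data.frame of grid coordinates (e.g. from
#'   \code{\link{makeGrid}}), carried through to the per-curve table.
#' @param fLo,fHi contact-point force window (see
#'   \code{\link{findContactPoint}}).
#' @param window Hertz fit window (see \code{\link{fitHertz}}).
#' @return A list: \code{fits} data.frame (curve, x, y, z0, E_kPa, rms,
#'   status, message), \code{summary} list (n, nFail, meanE, medianE),
#'   where statuses are \code{"ok"} or \code{"failed"}. Errors out when
#'   every fit fails.
#' @export
analyzeMap <- function(curves, coords = NULL, fLo = 0.10, fHi = 0.90,
                       window = c(0.10, 0.90)) {
  if (length(curves) < 1) stop("need at least one curve")
  ids <- names(curves)
  if (is.null(ids)) ids <- paste0("curve_", seq_along(curves))
  rows <- lapply(seq_along(curves), function(i) {
    res <- tryCatch({
      z0 <- findContactPoint(curves[[i]], fLo, fHi)
      fit <- fitHertz(curves[[i]], z0, window)
      data.frame(curve = ids[i], z0 = fit@z0, E_kPa = fit@E, rms = fit@rms,
                 status = "ok", message = "", stringsAsFactors = FALSE)
    }, calcimech_fit_error = function(e) {
      data.frame(curve = ids[i], z0 = NA_real_, E_kPa = NA_real_,
                 rms = NA_real_, status = "failed",
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(curve = ids[i], z0 = NA_real_, E_kPa = NA_real_,
                 rms = NA_real_, status = "failed",
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  fits <- do.call(rbind, rows)
  if (!is.null(coords)) {
    fits$x <- coords$x[seq_len(nrow(fits))]
    fits$y <- coords$y[seq_len(nrow(fits))]
  }
  ok <- fits$status == "ok"
  if (!any(ok)) {
    stop(paste0("all ", nrow(fits), " fits failed; first diagnostic: ",
                fits$message[1]))
  }
  list(fits = fits,
       summary = list(n = nrow(fits), nFail = sum(!ok),
                      meanE = mean(fits$E_kPa[ok]),
                      medianE = stats::median(fits$E_kPa[ok])))
}
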