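#' Construct a SAXSProfile
#'
#' @param q scattering vector (nm^-1), strictly increasing.
#' @param I intensities.
#' @param sigma optional uncertainties (NA if absent).
#' @param errorScale error-bar rescaling factor (default 1); this carries a
#'   externally estimated rescaling of the intensity error bars (e.g. from a
#'   Bayesian indirect Fourier transform) and multiplies sigma in fits.
#' @return A \linkS4class{SAXSProfile}.
#' @export
saxsProfile <- function(q, I, sigma = rep(NA_real_, length(q)),
                        errorScale = 1) {
  new("SAXSProfile", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma), errorScale = errorScale)
}

.sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

#' Debye-formula SAXS intensity of a conformer or ensemble
#'
#' Coarse forward model with one scattering centre per residue at the CA
#' position: I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij), with the i = j and
#' q r -> 0 limit equal to f_i f_j.  For an ensemble the per-frame profiles
#' are averaged under the frame weights (the ensemble profile is linear in
#' the weights).  Effective residue form factors default to 1 and are
#' q-independent; this is adequate for reweighting mechanics but is not an
#' atomic-form-factor model.
#'
#' @param x a \linkS4class{Conformer} or \linkS4class{ConformerEnsemble}.
#' @param q numeric grid of scattering vectors (nm^-1), nonempty.
#' @param formFactors numeric vector of per-residue effective amplitudes
#'   (> 0), recycled from length 1; or a named vector keyed by 3-letter
#'   residue code.
#' @param weights optional frame weights for ensembles (default prior
#'   weights).
#' @return A \linkS4class{SAXSProfile} (sigma absent).
#' @export
saxsDebye <- function(x, q, formFactors = 1, weights = NULL) {
  if (length(q) == 0) stop("q grid must be nonempty")
  if (any(q < 0)) stop("q must be >= 0")
  computeOne <- function(ca, f) {
    d <- as.matrix(stats::dist(ca))
    ff <- outer(f, f)
    vapply(q, function(qq) sum(ff * .sinc(qq * d)), numeric(1))
  }
  resolveF <- function(resnames) {
    if (!is.null(names(formFactors))) {
      f <- formFactors[resnames]
      if (any(is.na(f)))
        stop("formFactors lacks entries for some residue types")
    } else {
      f <- rep_len(formFactors, length(resnames))
    }
    if (any(f <= 0)) stop("form factors must be > 0")
    as.numeric(f)
  }
  if (is(x, "Conformer")) {
    ca <- x@coords[.caMatrix(x@atoms), , drop = FALSE]
    I <- computeOne(ca, resolveF(peptideSequence(x)))
  } else if (is(x, "ConformerEnsemble")) {
    if (is.null(weights)) weights <- x@weights
    stopifnot(length(weights) == nFrames(x))
    weights <- weights / sum(weights)
    f <- resolveF(peptideSequence(x))
    cai <- .caMatrix(x@atoms)
    I <- rep(0, length(q))
    for (k in seq_len(nFrames(x)))
      I <- I + weights[k] * computeOne(x@coords[cai, , k], f)
  } else stop("x must be a Conformer or a ConformerEnsemble")
  saxsProfile(q, I)
}

#' Per-frame calculated SAXS profile matrix
#'
#' Computes the Debye profile for every frame of an ensemble and returns the
#' frames x q matrix needed to build a \linkS4class{RestraintSet} for BME
#' reweighting.
#'
#' @inheritParams saxsDebye
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @return numeric matrix \code{[n_frames, length(q)]}.
#' @export
saxsPerFrameMatrix <- function(ensemble, q, formFactors = 1) {
  t(vapply(seq_len(nFrames(ensemble)), function(k) {
    saxsDebye(getConformer(ensemble, k), q, formFactors)@I
  }, numeric(length(q))))
}

#' Guinier fit of a SAXS profile
#'
#' Weighted linear regression of ln I on q^2 over the low-q window
#' satisfying q Rg <= \code{qRgLimit}, iterated to self-consistency
#' (\code{iterations} passes, standard practice for disordered proteins with
#' the default limit 1.3).  Rg = sqrt(-3 slope).
#'
#' @param profile a \linkS4class{SAXSProfile}.
#' @param qRgLimit upper limit on q Rg in the fit window (default 1.3).
#' @param iterations window-update passes (default 2).
#' @param minPoints minimum points in the fit window (default 5).
#' @return list with \code{rg} (nm, NA when the slope is positive),
#'   \code{I0}, \code{qRange}, \code{nPoints}, \code{r2} (coefficient of
#'   determination) and \code{converged}.
#' @export
guinierFit <- function(profile, qRgLimit = 1.3, iterations = 2,
                       minPoints = 5) {
  q <- profile@q
  I <- profile@I
  keep <- q > 0 & I > 0
  q <- q[keep]; I <- I[keep]
  sig <- profile@sigma[keep] * profile@errorScale
  w <- if (all(is.na(sig))) rep(1, length(q)) else (I / sig)^2  # d(lnI) = dI/I
  sel <- rep(TRUE, length(q))
  rg <- NA_real_
  for (it in seq_len(iterations + 1)) {
    if (sum(sel) < minPoints)
      stop(sprintf("fewer than %d points in the Guinier window", minPoints))
    fit <- stats::lm(log(I[sel]) ~ I(q[sel]^2), weights = w[sel])
    slope <- stats::coef(fit)[2]
    if (is.na(slope) || abs(slope) < 1e-12) slope <- 0  # flat profile: Rg = 0
    if (slope > 0) {
      return(list(rg = NA_real_, I0 = exp(stats::coef(fit)[1]),
                  qRange = range(q[sel]), nPoints = sum(sel), r2 = NA_real_,
                  converged = FALSE,
                  message = "positive Guinier slope: Rg undefined"))
    }
    rg <- sqrt(-3 * slope)
    if (it <= iterations) sel <- q * rg <= qRgLimit
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(rg = unname(rg), I0 = unname(exp(stats::coef(fit)[1])),
       qRange = range(q[sel]), nPoints = sum(sel), r2 = r2, converged = TRUE)
}

#' Scale/offset fit of a calculated SAXS profile to experiment
#'
#' Finds (a, b) minimizing sum_k [(I_exp - a I_calc - b)/sigma]^2 by
#' weighted linear least squares; with \code{offset = FALSE} only the scale
#' is fitted.  The calculated profile is linearly interpolated onto the
#' experimental q grid when the grids differ.
#'
#' @param calculated,experimental \linkS4class{SAXSProfile} objects; the
#'   experimental profile should carry uncertainties (unit weights are used
#'   when it does not).
#' @param offset fit a constant background term (default TRUE).
#' @return list with \code{scale}, \code{offset}, \code{chi2} (total),
#'   \code{chi2Reduced} (per point) and \code{fitted} (a I_calc + b on the
#'   experimental grid).
#' @export
fitScaleOffset <- function(calculated, experimental, offset = TRUE) {
  qe <- experimental@q
  Ic <- if (length(calculated@q) == length(qe) &&
            max(abs(calculated@q - qe)) < 1e-12) calculated@I
        else stats::approx(calculated@q, calculated@I, xout = qe)$y
  if (any(is.na(Ic)))
    stop("experimental q range extends beyond the calculated profile")
  if (stats::sd(Ic) < 1e-14 * max(abs(Ic), 1))
    stop("degenerate (constant) calculated profile: scale not identifiable")
  Ie <- experimental@I
  sig <- experimental@sigma * experimental@errorScale
  w <- if (all(is.na(sig))) rep(1, length(qe)) else 1 / sig^2
  fit <- if (offset) stats::lm(Ie ~ Ic, weights = w)
         else stats::lm(Ie ~ Ic + 0, weights = w)
  cf <- stats::coef(fit)
  a <- if (offset) cf[2] else cf[1]
  b <- if (offset) cf[1] else 0
  fitted <- a * Ic + b
  chi2 <- sum(w * (Ie - fitted)^2)
  list(scale = unname(a), offset = unname(b), chi2 = chi2,
       chi2Reduced = chi2 / length(qe), fitted = fitted)
}

#' Kirkwood hydrodynamic radius
#'
#' Kirkwood bead approximation from the CA scattering centres of one frame:
#' Rh^-1 = (1/N^2) sum_{i != j} r_ij^-1.  For an ensemble, 1/Rh is averaged
#' under the frame weights (mobilities average in fast exchange within a
#' subensemble), i.e. the ensemble Rh is the weighted harmonic mean.
#'
#' @param x a \linkS4class{Conformer} or \linkS4class{ConformerEnsemble}.
#' @param weights optional frame weights for ensembles.
#' @return Rh in nm.
#' @export
kirkwoodRh <- function(x, weights = NULL) {
  one <- function(ca) {
    N <- nrow(ca)
    if (N < 2) stop("Kirkwood Rh needs at least 2 centres")
    d <- stats::dist(ca)
    if (any(d < 1e-9))
      stop("coincident scattering centres give a divergent Kirkwood sum")
    invRh <- (1 / N^2) * 2 * sum(1 / d)
    1 / invRh
  }
  if (is(x, "Conformer"))
    return(one(x@coords[.caMatrix(x@atoms), , drop = FALSE]))
  stopifnot(is(x, "ConformerEnsemble"))
  if (is.null(weights)) weights <- x@weights
  weights <- weights / sum(weights)
  cai <- .caMatrix(x@atoms)
  invs <- vapply(seq_len(nFrames(x)),
                 function(k) 1 / one(x@coords[cai, , k]),
                 numeric(1))
  1 / sum(weights * invs)
}

#' Stokes-Einstein translational diffusion coefficient
#'
#' D = kB T / (6 pi eta Rh).  The default viscosity 1.138e-3 Pa s is that of
#' water at 288.15 K (15 degrees C), matching typical NMR diffusion
#' conditions for exchange-broadened systems.
#'
#' @param rh hydrodynamic radius in nm.
#' @param temperature kelvin.
#' @param viscosity solvent viscosity in Pa s.
#' @return D in m^2 s^-1.
#' @export
stokesEinsteinD <- function(rh, temperature = 288.15, viscosity = 1.138e-3) {
  stopifnot(rh > 0, temperature > 0, viscosity > 0)
  kB <- 1.380649e-23
  kB * temperature / (6 * pi * viscosity * rh * 1e-9)
}
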