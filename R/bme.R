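#' Construct a RestraintSet
#'
#' @param observed experimental values o_j.
#' @param sigma uncertainties sigma_j > 0.
#' @param calc matrix of calculated observables, frames x restraints.
#' @param labels optional restraint labels.
#' @return A \linkS4class{RestraintSet}.
#' @export
restraintSet <- function(observed, sigma, calc, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("r%d", seq_along(observed))
  new("RestraintSet", labels = labels, observed = as.numeric(observed),
      sigma = as.numeric(sigma), calc = as.matrix(calc))
}

#' Chi-squared of weighted ensemble averages against restraints
#'
#' sum_j [(sum_i w_i F_ij - o_j) / sigma_j]^2.
#'
#' @param weights normalized frame weights.
#' @param restraints a \linkS4class{RestraintSet}.
#' @return non-negative scalar.
#' @export
chi2Restraints <- function(weights, restraints) {
  stopifnot(length(weights) == nrow(restraints@calc))
  avg <- as.numeric(crossprod(restraints@calc, weights))
  sum(((avg - restraints@observed) / restraints@sigma)^2)
}

# dual function Gamma(lambda) and its analytic gradient; the posterior
# weights for a given lambda are w0 * exp(-F lambda) / Z
.bmeDual <- function(lambda, w0, Fm, o, sig2, theta) {
  e <- -as.numeric(Fm %*% lambda)
  m <- max(e)
  Z <- sum(w0 * exp(e - m))
  lnZ <- m + log(Z)
  lnZ + sum(lambda * o) + (theta / 2) * sum(lambda^2 * sig2)
}

.bmeGrad <- function(lambda, w0, Fm, o, sig2, theta) {
  e <- -as.numeric(Fm %*% lambda)
  m <- max(e)
  w <- w0 * exp(e - m)
  w <- w / sum(w)
  avg <- as.numeric(crossprod(Fm, w))
  -avg + o + theta * lambda * sig2
}

.bmeHess <- function(lambda, w0, Fm, sig2, theta) {
  e <- -as.numeric(Fm %*% lambda)
  w <- w0 * exp(e - max(e))
  w <- w / sum(w)
  avg <- as.numeric(crossprod(Fm, w))
  Fc <- sweep(Fm, 2, avg)
  crossprod(Fc, w * Fc) + diag(theta * sig2, length(sig2))
}

.bmeWeights <- function(lambda, w0, Fm) {
  e <- -as.numeric(Fm %*% lambda)
  w <- w0 * exp(e - max(e))
  w[w < 1e-300] <- 0
  w / sum(w)
}

#' Bayesian/maximum-entropy reweighting
#'
#' Minimally perturbs prior frame weights w0 so that weighted ensemble
#' averages of the calculated observables approach the experimental values,
#' balancing fit quality against the Kullback-Leibler divergence from the
#' prior via the confidence parameter theta.  The posterior has the
#' exponential form w_i(lambda) = w0_i exp(-sum_j lambda_j F_ij)/Z(lambda),
#' and lambda is found by minimizing the convex dual
#' Gamma(lambda) = ln Z + sum_j lambda_j o_j + (theta/2) sum_j
#' lambda_j^2 sigma_j^2 with quasi-Newton (BFGS) iterations from lambda = 0
#' using the analytic gradient -<F_j>_w + o_j + theta lambda_j sigma_j^2.
#'
#' @param priorWeights normalized prior weights w0.
#' @param restraints a \linkS4class{RestraintSet}.
#' @param theta confidence parameter, > 0; large theta returns the prior,
#'   small theta enforces the restraints.
#' @param maxit maximum BFGS iterations.
#' @param gradTol convergence threshold on the gradient norm.
#' @return A \linkS4class{BMEResult}.
#' @export
fitBME <- function(priorWeights, restraints, theta, maxit = 500,
                   gradTol = 1e-8) {
  if (theta <= 0) stop("theta must be > 0")
  w0 <- priorWeights
  if (any(w0 < 0) || abs(sum(w0) - 1) > 1e-9)
    stop("prior weights must be non-negative and normalized")
  w0 <- w0 / sum(w0)
  Fm <- restraints@calc
  if (nrow(Fm) != length(w0))
    stop("prior weights and calculated observables disagree on ensemble size")
  o <- restraints@observed
  sig2 <- restraints@sigma^2
  lambda <- rep(0, length(o))
  gn <- Inf
  # convergence is judged on the gradient norm relative to the scale of
  # the observables, so profiles in arbitrary intensity units behave like
  # O(1) restraints
  gradScale <- max(1, sqrt(sum(o^2)))
  # BFGS occasionally stalls a hair above the tolerance; restarting from
  # the current iterate polishes the solution
  for (round in 1:4) {
    opt <- stats::optim(lambda, fn = .bmeDual, gr = .bmeGrad,
                        w0 = w0, Fm = Fm, o = o, sig2 = sig2, theta = theta,
                        method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-15))
    lambda <- opt$par
    gn <- sqrt(sum(.bmeGrad(lambda, w0, Fm, o, sig2, theta)^2))
    if (gn < gradTol * gradScale) break
  }
  # Newton polish: the dual Hessian Cov_w(F) + theta diag(sigma^2) is
  # positive definite, so a few damped Newton steps reach machine precision
  for (it in 1:30) {
    g <- .bmeGrad(lambda, w0, Fm, o, sig2, theta)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12 * gradScale) break
    H <- .bmeHess(lambda, w0, Fm, sig2, theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- .bmeDual(lambda, w0, Fm, o, sig2, theta)
    damp <- 1
    while (damp > 1e-4 &&
           .bmeDual(lambda - damp * step, w0, Fm, o, sig2, theta) > f0)
      damp <- damp / 2
    lambda <- lambda - damp * step
  }
  gn <- sqrt(sum(.bmeGrad(lambda, w0, Fm, o, sig2, theta)^2))
  converged <- gn < gradTol * gradScale
  if (!converged)
    warning(sprintf("BME dual not converged to tolerance: |grad| = %.3e", gn))
  w <- .bmeWeights(lambda, w0, Fm)
  pos <- w > 0
  sRel <- -sum(w[pos] * log(w[pos] / w0[pos]))
  new("BMEResult", lambda = lambda, weights = w, priorWeights = w0,
      chi2Prior = chi2Restraints(w0, restraints),
      chi2Posterior = chi2Restraints(w, restraints),
      sRel = sRel, phiEff = min(exp(sRel), 1), theta = theta,
      converged = converged, gradNorm = gn)
}

#' Scan BME over a theta grid
#'
#' Repeats \code{\link{fitBME}} over a positive sorted theta grid and
#' tabulates the fit-quality/entropy trade-off; used to choose theta at the
#' elbow of the curve.  Fit errors at one theta are reported and the scan
#' continues.
#'
#' @inheritParams fitBME
#' @param thetaGrid positive, sorted increasing.
#' @return data.frame with columns \code{theta}, \code{chi2Posterior},
#'   \code{chi2Reduced}, \code{phiEff}, \code{converged}.
#' @export
thetaScan <- function(priorWeights, restraints, thetaGrid) {
  if (any(thetaGrid <= 0) || is.unsorted(thetaGrid))
    stop("thetaGrid must be positive and sorted increasing")
  m <- length(restraints@observed)
  rows <- lapply(thetaGrid, function(th) {
    res <- tryCatch(fitBME(priorWeights, restraints, th),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(theta = th, chi2Posterior = NA_real_,
                        chi2Reduced = NA_real_, phiEff = NA_real_,
                        converged = FALSE))
    data.frame(theta = th, chi2Posterior = res@chi2Posterior,
               chi2Reduced = res@chi2Posterior / m, phiEff = res@phiEff,
               converged = res@converged)
  })
  do.call(rbind, rows)
}

#' Select theta from a scan by the minimal-perturbation criterion
#'
#' Returns the largest theta whose reduced posterior chi-squared is at or
#' below \code{chi2Max} (default 1.2); if none qualifies, the theta with the
#' smallest reduced chi-squared.  Larger theta means smaller perturbation of
#' the prior, so this picks the gentlest reweighting that still fits.
#'
#' @param scan data.frame from \code{\link{thetaScan}}.
#' @param chi2Max reduced chi-squared threshold.
#' @return selected theta (scalar).
#' @export
selectTheta <- function(scan, chi2Max = 1.2) {
  ok <- !is.na(scan$chi2Reduced)
  if (!any(ok)) stop("no successful fits in the scan")
  good <- ok & scan$chi2Reduced <= chi2Max
  if (any(good)) max(scan$theta[good])
  else scan$theta[ok][which.min(scan$chi2Reduced[ok])]
}

#' BME reweighting of an ensemble against an experimental SAXS profile
#'
#' Builds SAXS restraints from per-frame Debye profiles and the experimental
#' curve, and alternates scale/offset refitting of the calculated intensities
#' with BME weight updates (\code{rounds} rounds, default 5), mirroring
#' standard BME-SAXS practice: the scale and offset are refit under the
#' current posterior weights, the restraints are updated, and lambda is
#' re-optimized.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param experimental a \linkS4class{SAXSProfile} with uncertainties.
#' @param theta confidence parameter (see \code{\link{fitBME}}); default 10.
#' @param formFactors per-residue effective amplitudes (see
#'   \code{\link{saxsDebye}}).
#' @param rounds alternating scale/offset + reweight rounds.
#' @param offset include a constant background in the scale fit.
#' @return list with \code{result} (a \linkS4class{BMEResult}),
#'   \code{scale}, \code{offset}, and \code{restraints} (the final
#'   \linkS4class{RestraintSet} on the experimental grid).
#' @export
reweightSAXS <- function(ensemble, experimental, theta = 10,
                         formFactors = 1, rounds = 5, offset = TRUE) {
  if (all(is.na(experimental@sigma)))
    stop("experimental SAXS profile must carry uncertainties")
  q <- experimental@q
  Fm <- saxsPerFrameMatrix(ensemble, q, formFactors)
  w <- ensemble@weights
  sig <- experimental@sigma * experimental@errorScale
  res <- NULL; a <- 1; b <- 0
  for (r in seq_len(rounds)) {
    avg <- as.numeric(crossprod(Fm, w))
    sf <- fitScaleOffset(saxsProfile(q, avg), experimental, offset = offset)
    a <- sf$scale; b <- sf$offset
    rs <- restraintSet(observed = experimental@I,
                       sigma = sig,
                       calc = a * Fm + b,
                       labels = sprintf("q=%.4g", q))
    res <- fitBME(ensemble@weights, rs, theta)
    w <- res@weights
  }
  list(result = res, scale = a, offset = b, restraints = rs)
}
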