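#' Physical constants for 15N backbone relaxation analysis
#'
#' Derived dipolar and CSA interaction constants for an amide 15N-1H spin
#' pair at a given static field.  Defaults: N-H bond length 1.02 Angstrom,
#' 15N CSA -160 ppm, standard gyromagnetic ratios.  The dipolar constant is
#' d = (mu0/4pi) hbar gammaH gammaN / r^3 (rad/s) and the CSA constant
#' c^2 = (omegaN deltaSigma)^2 / 3.
#'
#' @param B0 static magnetic field in tesla (14.1 T is a 600 MHz magnet).
#' @param rNH N-H bond length in m.
#' @param deltaSigma 15N CSA in ppm.
#' @param gammaH,gammaN gyromagnetic ratios in rad s^-1 T^-1 (gammaN is
#'   negative).
#' @return list with \code{B0}, \code{omegaH}, \code{omegaN} (rad/s,
#'   magnitudes), \code{d2}, \code{c2}, \code{gammaH}, \code{gammaN}.
#' @export
relaxationConstants <- function(B0 = 14.1, rNH = 1.02e-10,
                                deltaSigma = -160, gammaH = 2.6752218744e8,
                                gammaN = -2.7126e7) {
  mu0 <- 4 * pi * 1e-7
  hbar <- 1.054571817e-34
  d <- (mu0 / (4 * pi)) * hbar * gammaH * gammaN / rNH^3
  omegaH <- gammaH * B0
  omegaN <- abs(gammaN) * B0
  list(B0 = B0, omegaH = omegaH, omegaN = omegaN,
       d2 = d^2, c2 = (omegaN * deltaSigma * 1e-6)^2 / 3,
       gammaH = gammaH, gammaN = gammaN)
}

#' Fit a monoexponential decay
#'
#' Nonlinear least squares of I(t) = I0 exp(-R t), initialized from the
#' log-linear regression; standard errors from the fit covariance.
#' Non-decaying data yield R <= 0 with a warning.
#'
#' @param delays times in s (>= 3).
#' @param intensities observed intensities.
#' @param uncertainties optional per-point standard deviations (used as
#'   weights 1/sigma^2).
#' @return list with \code{rate} (s^-1), \code{rateSE}, \code{I0},
#'   \code{I0SE}, \code{fitted}.
#' @export
fitMonoexponential <- function(delays, intensities, uncertainties = NULL) {
  if (length(delays) < 3) stop("need at least 3 delays")
  stopifnot(length(intensities) == length(delays))
  pos <- intensities > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(intensities[pos]) ~ delays[pos])
    start <- list(I0 = unname(exp(stats::coef(lf)[1])),
                  R = -unname(stats::coef(lf)[2]))
  } else {
    start <- list(I0 = max(abs(intensities)), R = 1 / max(delays))
  }
  if (start$R <= 1e-10) {
    warning("non-decaying data: fitted rate <= 0")
    return(list(rate = start$R, rateSE = NA_real_, I0 = start$I0,
                I0SE = NA_real_,
                fitted = start$I0 * exp(-start$R * delays)))
  }
  args <- list(intensities ~ I0 * exp(-R * delays),
               start = start, data = list(intensities = intensities,
                                          delays = delays),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(uncertainties)) args$weights <- 1 / uncertainties^2
  fit <- tryCatch(suppressWarnings(do.call(minpack.lm::nlsLM, args)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("nonlinear fit failed; reporting log-linear estimate")
    out <- list(rate = start$R, rateSE = NA_real_, I0 = start$I0,
                I0SE = NA_real_,
                fitted = start$I0 * exp(-start$R * delays))
  } else {
    cf <- summary(fit)$coefficients
    out <- list(rate = unname(cf["R", "Estimate"]),
                rateSE = unname(cf["R", "Std. Error"]),
                I0 = unname(cf["I0", "Estimate"]),
                I0SE = unname(cf["I0", "Std. Error"]),
                fitted = stats::fitted(fit))
  }
  if (out$rate <= 1e-10) warning("non-decaying data: fitted rate <= 0")
  out
}

#' R2 from R1rho and R1 with the rotating-frame tilt angle
#'
#' R2 = (R1rho - R1 cos^2 theta) / sin^2 theta, with standard errors
#' propagated in quadrature.
#'
#' @param r1rho,r1 rates in s^-1.
#' @param tilt tilt angle theta in degrees, in (0, 90].
#' @param r1rhoSE,r1SE standard errors (default 0).
#' @return list with \code{r2}, \code{r2SE}.
#' @export
r2FromR1rho <- function(r1rho, r1, tilt, r1rhoSE = 0, r1SE = 0) {
  if (any(tilt <= 0 | tilt > 90)) stop("tilt must lie in (0, 90] degrees")
  s2 <- sin(.deg2rad(tilt))^2
  c2 <- cos(.deg2rad(tilt))^2
  if (any(s2 < 1e-6)) stop("sin^2(tilt) too small: R2 not identifiable")
  list(r2 = (r1rho - r1 * c2) / s2,
       r2SE = sqrt(r1rhoSE^2 + (c2 * r1SE)^2) / s2)
}

#' Steady-state heteronuclear NOE from saturated/reference intensities
#'
#' NOE = I_sat / I_ref with first-order error propagation from the spectral
#' noise standard deviations.
#'
#' @param iSat,iRef peak intensities.
#' @param sigmaSat,sigmaRef noise standard deviations (default 0).
#' @return list with \code{noe}, \code{noeSE}.
#' @export
hetNOE <- function(iSat, iRef, sigmaSat = 0, sigmaRef = 0) {
  if (any(iRef == 0)) stop("reference intensity must be nonzero")
  noe <- iSat / iRef
  se <- sqrt((sigmaSat / iRef)^2 + (iSat * sigmaRef / iRef^2)^2)
  list(noe = noe, noeSE = se)
}

#' Forward 15N relaxation rates from a spectral density function
#'
#' Computes (R1, R2, NOE) from a model spectral density J(omega) using the
#' standard dipolar + CSA expressions at exact frequencies.  This is the
#' forward counterpart of \code{\link{reducedSpectralDensity}}; mapping its
#' output back recovers the J values to within the high-frequency
#' approximation.
#'
#' @param J function of angular frequency (rad/s) returning spectral
#'   density in s/rad; e.g. a single-Lorentzian
#'   \code{function(w) 0.4 * tau / (1 + (w * tau)^2)}.
#' @param constants from \code{\link{relaxationConstants}}.
#' @return list with \code{r1}, \code{r2}, \code{noe}, \code{sigmaNH}.
#' @export
forwardRelaxationRates <- function(J, constants = relaxationConstants()) {
  wN <- constants$omegaN
  wH <- constants$omegaH
  d2 <- constants$d2
  c2 <- constants$c2
  r1 <- (d2 / 4) * (3 * J(wN) + J(wH - wN) + 6 * J(wH + wN)) + c2 * J(wN)
  r2 <- (d2 / 8) * (4 * J(0) + 3 * J(wN) + J(wH - wN) + 6 * J(wH) +
                      6 * J(wH + wN)) + (c2 / 6) * (4 * J(0) + 3 * J(wN))
  sigmaNH <- (d2 / 4) * (6 * J(wH + wN) - J(wH - wN))
  noe <- 1 + (constants$gammaH / constants$gammaN) * (sigmaNH / r1)
  list(r1 = r1, r2 = r2, noe = noe, sigmaNH = sigmaNH)
}

#' Reduced spectral density mapping
#'
#' Maps measured (R1, R2, NOE) at one field to J(0), J(omegaN) and
#' J(0.87 omegaH) under the high-frequency approximation
#' J(omegaH - omegaN) = J(omegaH) = J(omegaH + omegaN) = J(0.87 omegaH):
#' sigmaNH = R1 (NOE - 1) (gammaN/gammaH);
#' J(0.87 omegaH) = 4 sigmaNH / (5 d^2);
#' J(omegaN) = (R1 - 7 (d^2/4) J(0.87 omegaH)) / (3 d^2/4 + c^2);
#' J(0) = (R2 - (13 d^2/8) J(0.87 omegaH) - (3 d^2/8 + c^2/2) J(omegaN)) /
#' (d^2/2 + 2 c^2/3).  The coefficient set is pinned by the round trip
#' against \code{\link{forwardRelaxationRates}}.
#'
#' @param r1,r2,noe measured rates (s^-1) and heteronuclear NOE.
#' @param constants from \code{\link{relaxationConstants}}.
#' @return list with \code{J0}, \code{JwN}, \code{JwH} (s/rad) and
#'   \code{sigmaNH}.
#' @export
reducedSpectralDensity <- function(r1, r2, noe,
                                   constants = relaxationConstants()) {
  d2 <- constants$d2
  c2 <- constants$c2
  if (any(noe > 1))
    warning("NOE > 1 with 15N implies an inverted cross-relaxation sign")
  sigmaNH <- r1 * (noe - 1) * (constants$gammaN / constants$gammaH)
  JwH <- 4 * sigmaNH / (5 * d2)
  JwN <- (r1 - 7 * (d2 / 4) * JwH) / (3 * d2 / 4 + c2)
  J0 <- (r2 - (13 * d2 / 8) * JwH - (3 * d2 / 8 + c2 / 2) * JwN) /
    (d2 / 2 + 2 * c2 / 3)
  list(J0 = J0, JwN = JwN, JwH = JwH, sigmaNH = sigmaNH)
}

#' Exchange contribution to transverse relaxation
#'
#' Rex = R2 - kappa Rdd, comparing the measured R2 with the scaled
#' exchange-free dipolar rate Rdd; errors propagate in quadrature and
#' |Rex| < 2 SE is flagged as no detectable exchange.
#'
#' @param r2 transverse rate (s^-1); \code{rdd} exchange-free rate.
#' @param rdd exchange-free relaxation rate (s^-1).
#' @param kappa positive scale matching Rdd to R2 conditions (default 1).
#' @param r2SE,rddSE standard errors.
#' @return list with \code{rex}, \code{rexSE}, \code{noExchange}.
#' @export
exchangeContribution <- function(r2, rdd, kappa = 1, r2SE = 0, rddSE = 0) {
  if (kappa <= 0) stop("kappa must be > 0")
  rex <- r2 - kappa * rdd
  se <- sqrt(r2SE^2 + (kappa * rddSE)^2)
  list(rex = rex, rexSE = se, noExchange = abs(rex) < 2 * se)
}

#' Stejskal-Tanner fit of a DOSY decay
#'
#' Nonlinear least squares of I(g) = I0 exp(-D gamma^2 g^2 delta^2
#' (Delta - delta/3)), initialized from the log-linear regression; the fit
#' is invariant under rescaling all intensities.
#'
#' @param series data.frame with columns \code{gradient} (T/m) and
#'   \code{intensity}, e.g. from \code{\link{dosyDecayTable}}; acquisition
#'   parameters are read from attributes or the explicit arguments.
#' @param delta gradient pulse length in s.
#' @param Delta diffusion delay in s.
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1.
#' @return list with \code{D} (m^2/s), \code{DSE}, \code{I0},
#'   \code{fitted}.
#' @export
stejskalTannerFit <- function(series, delta = attr(series, "delta"),
                              Delta = attr(series, "Delta"),
                              gamma = attr(series, "gamma")) {
  if (is.null(delta) || is.null(Delta) || is.null(gamma))
    stop("delta, Delta and gamma must be supplied (or set as attributes)")
  if (nrow(series) < 4) stop("need at least 4 gradient points")
  stopifnot(Delta > delta / 3)
  b <- gamma^2 * series$gradient^2 * delta^2 * (Delta - delta / 3)
  I <- series$intensity
  # b values are huge in SI units; fit D on a 1e-10 m^2/s scale for
  # conditioning, then rescale
  bs <- b * 1e-10
  pos <- I > 0
  if (sum(pos) < 2) stop("non-decaying or nonpositive intensity series")
  lf <- stats::lm(log(I[pos]) ~ bs[pos])
  start <- list(I0 = exp(unname(stats::coef(lf)[1])),
                Ds = max(-unname(stats::coef(lf)[2]), 0))
  if (start$Ds <= 1e-12) {
    warning("non-decaying series: D = 0")
    return(list(D = 0, DSE = NA_real_, I0 = start$I0,
                fitted = rep(start$I0, length(bs))))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 * exp(-Ds * bs), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("nonlinear fit failed; reporting log-linear estimate")
    return(list(D = start$Ds * 1e-10, DSE = NA_real_, I0 = start$I0,
                fitted = start$I0 * exp(-start$Ds * bs)))
  }
  cf <- summary(fit)$coefficients
  list(D = unname(cf["Ds", "Estimate"]) * 1e-10,
       DSE = unname(cf["Ds", "Std. Error"]) * 1e-10,
       I0 = unname(cf["I0", "Estimate"]),
       fitted = stats::fitted(fit))
}

#' One-tailed Welch's t-test from summary statistics
#'
#' Textbook Welch statistic t = (m1 - m2)/sqrt(s1^2/n1 + s2^2/n2) with the
#' Welch-Satterthwaite degrees of freedom; the tail direction must be
#' declared explicitly to avoid silent sign errors.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param direction \code{"greater"} tests mean1 > mean2, \code{"less"}
#'   tests mean1 < mean2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchTOneTailed <- function(mean1, sd1, n1, mean2, sd2, n2,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- if (direction == "greater") stats::pt(t, df, lower.tail = FALSE)
       else stats::pt(t, df)
  list(t = t, df = df, p = p)
}

#' Monte Carlo uncertainty propagation for a fit
#'
#' Resamples the data with Gaussian noise at the stated uncertainties,
#' refits, and returns the standard deviation of the refit parameters.
#'
#' @param fitFun function taking a numeric data vector and returning a
#'   named numeric vector of fitted parameters.
#' @param data observed numeric vector.
#' @param uncertainties per-point standard deviations (scalar or vector).
#' @param nDraws number of resamples (>= 100).
#' @param seed random seed (reproducible).
#' @return named numeric vector of parameter standard deviations.
#' @export
montecarloErrors <- function(fitFun, data, uncertainties, nDraws = 500,
                             seed = 1L) {
  if (nDraws < 100) stop("use at least 100 draws")
  uncertainties <- rep_len(uncertainties, length(data))
  proto <- fitFun(data)
  draws <- .withSeed(seed, {
    vapply(seq_len(nDraws), function(i) {
      fitFun(data + stats::rnorm(length(data), 0, uncertainties))
    }, proto)
  })
  if (is.null(dim(draws)))
    draws <- matrix(draws, nrow = 1, dimnames = list(names(proto), NULL))
  apply(draws, 1, stats::sd)
}
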