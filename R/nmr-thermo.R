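.RGAS <- 8.314  # J K^-1 mol^-1

#' Cis population from slow-exchange peak quantifications
#'
#' In the slow-exchange regime the cis and trans peaks of a residue report
#' their state concentrations, so p = V_cis / (V_cis + V_trans) per residue.
#' The aggregate is the mean and sample standard deviation across residues.
#' Residues missing either isomer peak are excluded and reported.
#'
#' @param quantifications data.frame with columns \code{residue},
#'   \code{isomer} ("cis"/"trans") and a value column (at one temperature).
#' @param statistic which value column to use: \code{"volume"} or
#'   \code{"height"}.
#' @param residues optional subset of residues to aggregate over.
#' @return list with \code{mean}, \code{sd}, \code{perResidue} (named
#'   fractions), \code{excluded}.
#' @export
cisPopulation <- function(quantifications, statistic = c("volume", "height"),
                          residues = NULL) {
  statistic <- match.arg(statistic)
  if (!statistic %in% names(quantifications))
    stop(sprintf("column '%s' not found", statistic))
  df <- quantifications
  if (!is.null(residues)) df <- df[df$residue %in% residues, ]
  res <- unique(df$residue)
  p <- rep(NA_real_, length(res)); names(p) <- res
  for (r in res) {
    vc <- df[[statistic]][df$residue == r & df$isomer == "cis"]
    vt <- df[[statistic]][df$residue == r & df$isomer == "trans"]
    if (length(vc) == 1 && length(vt) == 1 && vc > 0 && vt > 0)
      p[r] <- vc / (vc + vt)
  }
  excluded <- names(p)[is.na(p)]
  if (length(excluded))
    message("residues excluded (missing isomer peak): ",
            paste(excluded, collapse = ", "))
  p <- p[!is.na(p)]
  list(mean = mean(p), sd = if (length(p) > 1) stats::sd(p) else NA_real_,
       perResidue = p, excluded = excluded)
}

#' Equilibrium constant of the cis/trans equilibrium
#'
#' K = [cis]/[trans] = p / (1 - p); \code{cisFractionFromK} is the inverse
#' p = K / (1 + K).
#'
#' @param p cis fraction in (0, 1).
#' @return K > 0.
#' @export
equilibriumConstant <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  p / (1 - p)
}

#' @rdname equilibriumConstant
#' @param K equilibrium constant > 0.
#' @export
cisFractionFromK <- function(K) {
  stopifnot(all(K > 0))
  K / (1 + K)
}

#' Van 't Hoff fit of equilibrium constants versus temperature
#'
#' Weighted linear least squares of ln K on 1/T:
#' ln K = -dH/(R T) + dS/R, so dH = -R slope and dS = R intercept
#' (R = 8.314 J K^-1 mol^-1).  Standard errors come from the regression
#' covariance.
#'
#' @param temperatures kelvin, >= 3 values.
#' @param K equilibrium constants (> 0).
#' @param lnKSigma optional uncertainties of ln K used as weights
#'   1/sigma^2.
#' @return list with \code{dH} (J/mol), \code{dHSE}, \code{dS}
#'   (J/(K mol)), \code{dSSE}, \code{residuals}, \code{nTemperatures},
#'   \code{fit} (the lm object).
#' @export
vantHoffFit <- function(temperatures, K, lnKSigma = NULL) {
  if (length(temperatures) < 3) stop("need at least 3 temperatures")
  stopifnot(length(K) == length(temperatures), all(K > 0),
            all(temperatures > 0))
  x <- 1 / temperatures
  y <- log(K)
  w <- if (is.null(lnKSigma)) NULL else 1 / lnKSigma^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  # noiseless input gives an exact fit; the SE computation is still defined
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  list(dH = unname(-.RGAS * cf[2]), dHSE = unname(.RGAS * se[2]),
       dS = unname(.RGAS * cf[1]), dSSE = unname(.RGAS * se[1]),
       residuals = unname(stats::residuals(fit)),
       nTemperatures = length(temperatures), fit = fit)
}

#' Cis population predicted from van 't Hoff parameters
#'
#' K(T) = exp(-(dH - T dS)/(R T)) and p = K/(1 + K).
#'
#' @param dH enthalpy difference (cis minus trans), J/mol.
#' @param dS entropy difference, J/(K mol).
#' @param temperature kelvin (> 0); 37 degrees C is 310.15 K.
#' @return cis fraction in (0, 1).
#' @examples
#' populationAtTemperature(16000, 34, 310.15)  # about 0.108
#' @export
populationAtTemperature <- function(dH, dS, temperature) {
  stopifnot(all(temperature > 0))
  K <- exp(-(dH - temperature * dS) / (.RGAS * temperature))
  cisFractionFromK(K)
}

#' Amide-proton temperature coefficient
#'
#' Least-squares slope of the 1HN chemical shift against temperature in
#' ppb/K.  Slopes more negative than -4.5 ppb/K indicate an amide proton
#' not involved in a persistent intramolecular hydrogen bond.
#'
#' @param temperatures kelvin (>= 3).
#' @param shifts 1HN chemical shifts in ppm.
#' @return list with \code{slope} (ppb/K), \code{slopeSE}, \code{flag}
#'   ("no persistent H-bond" when slope < -4.5 ppb/K, otherwise
#'   "possible H-bond").
#' @export
temperatureCoefficient <- function(temperatures, shifts) {
  if (length(temperatures) < 3) stop("need at least 3 temperatures")
  fit <- stats::lm(shifts ~ temperatures)
  slope <- unname(stats::coef(fit)[2]) * 1000  # ppm/K -> ppb/K
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[2] * 1000)
  list(slope = slope, slopeSE = unname(se),
       flag = if (slope < -4.5) "no persistent H-bond" else "possible H-bond")
}

#' Proline isomer from side-chain carbon shifts
#'
#' The 13Cb - 13Cg chemical-shift difference is diagnostic of the proline
#' peptide-bond conformation: near 9.5 ppm for cis, near 4.5 ppm for trans.
#' A conservative band assigns cis for differences >= 8 ppm, trans for
#' <= 6 ppm, ambiguous between.
#'
#' @param deltaCB,deltaCG 13C chemical shifts in ppm.
#' @return \code{"cis"}, \code{"trans"} or \code{"ambiguous"} (vectorized).
#' @export
prolineIsomerFromShifts <- function(deltaCB, deltaCG) {
  d <- deltaCB - deltaCG
  stopifnot(all(is.finite(d)))
  ifelse(d >= 8, "cis", ifelse(d <= 6, "trans", "ambiguous"))
}

#' Random-coil and secondary chemical-shift references
#'
#' Reads the reference table shipped with the package (or a user-supplied
#' CSV with the same columns): per residue type, random-coil shifts for
#' 1Ha/13Ca/13Cb and the full-helix/full-strand secondary shift offsets
#' used to normalize SSP scores.  Shipping the table as an editable CSV
#' makes the reference choice user-visible, since it materially affects
#' the scores.
#'
#' @param path CSV path; default the packaged table.
#' @return data.frame with columns \code{resname}, \code{nucleus},
#'   \code{coil}, \code{helix}, \code{strand} (ppm).
#' @export
shiftReferences <- function(path = system.file("extdata",
                                               "random_coil_shifts.csv",
                                               package = "ProlineEnsembles")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Secondary structure propensity (SSP) score
#'
#' Windowed, multi-nucleus secondary-shift score per residue: within each
#' window the observed secondary shifts (observed minus random coil) are
#' summed over residues and nuclei and normalized by the corresponding
#' full-helix (when the sum is positive) or full-strand (negative)
#' reference secondary shifts, giving +1 for full helix, -1 for full
#' strand, 0 for coil; scores are capped to [-1, 1].  Missing nuclei are
#' excluded from the affected residue's sums.
#'
#' @param shifts data.frame with columns \code{resid}, \code{resname},
#'   \code{nucleus} (one of \code{"HA"}, \code{"CA"}, \code{"CB"}),
#'   \code{observed} (ppm).
#' @param references reference table from \code{\link{shiftReferences}}.
#' @param window odd window length in residues (default 5), truncated at
#'   the chain ends.
#' @return data.frame with columns \code{resid}, \code{ssp}.
#' @export
sspScore <- function(shifts, references = shiftReferences(), window = 5) {
  if (window %% 2 != 1) stop("window must be odd")
  ref <- merge(shifts, references, by = c("resname", "nucleus"),
               all.x = TRUE)
  if (any(is.na(ref$coil)))
    stop("reference table lacks entries for some residue/nucleus pairs")
  ref$sec <- ref$observed - ref$coil
  ref$dHelix <- ref$helix - ref$coil
  ref$dStrand <- ref$strand - ref$coil
  resids <- sort(unique(ref$resid))
  half <- (window - 1) / 2
  ssp <- vapply(resids, function(r) {
    inW <- ref$resid >= r - half & ref$resid <= r + half
    num <- sum(ref$sec[inW])
    # positive sums are scored against the magnitude of the full-helix
    # reference sum, negative sums against the full-strand magnitude
    den <- if (num >= 0) abs(sum(ref$dHelix[inW]))
           else abs(sum(ref$dStrand[inW]))
    if (den < 1e-12) return(0)
    max(-1, min(1, num / den))
  }, numeric(1))
  data.frame(resid = resids, ssp = ssp)
}
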