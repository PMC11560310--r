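#' Split an ensemble into cis and trans proline subensembles
#'
#' Classifies every frame by the omega torsion about the peptide bond
#' preceding \code{prolineResid} and returns the two subensembles with
#' weights renormalized within each, together with the raw populations
#' (sums of prior weights, which add to 1 exactly).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param prolineResid 1-based residue index of the proline.
#' @return list with \code{populations} (named numeric, cis/trans),
#'   \code{labels} (per frame), and \code{cis}/\code{trans}
#'   (\linkS4class{ConformerEnsemble} or NULL when the subensemble is
#'   empty).
#' @export
splitByIsomer <- function(ensemble, prolineResid) {
  atoms <- ensemble@atoms
  if (atoms$resname[match(prolineResid, atoms$resid)] != "PRO")
    stop(sprintf("residue %d is not a proline", prolineResid))
  om <- omegaSeries(ensemble, prolineResid)
  lab <- classifyIsomer(om)
  w <- ensemble@weights
  pops <- c(cis = sum(w[lab == "cis"]), trans = sum(w[lab == "trans"]))
  sub <- function(which) {
    sel <- lab == which
    if (!any(sel)) return(NULL)
    new("ConformerEnsemble", atoms = atoms,
        coords = ensemble@coords[, , sel, drop = FALSE],
        weights = w[sel] / sum(w[sel]),
        metadata = c(ensemble@metadata, list(isomerSubset = which)))
  }
  list(populations = pops, labels = lab, cis = sub("cis"),
       trans = sub("trans"))
}

#' Weighted Gaussian kernel density estimate
#'
#' density(x) = sum_i w_i K_h(x - v_i) with a Gaussian kernel, evaluated by
#' direct summation on an explicit grid (exact, so mixture decompositions
#' hold to machine precision).  The default bandwidth is Silverman's rule
#' evaluated at the weighted effective sample size n_eff = 1/sum(w^2).
#' Zero-variance input returns a near-delta centred on the common value.
#'
#' @param values sample values.
#' @param weights sample weights (default uniform), normalized internally.
#' @param bandwidth kernel standard deviation; default Silverman.
#' @param grid evaluation grid; default 512 points spanning the data plus
#'   4 bandwidths.
#' @return list with \code{grid}, \code{density}, \code{bandwidth}.
#' @export
weightedKDE <- function(values, weights = NULL, bandwidth = NULL,
                        grid = NULL) {
  n <- length(values)
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- weights / sum(weights)
  if (is.null(bandwidth)) {
    neff <- 1 / sum(weights^2)
    mu <- sum(weights * values)
    sdw <- sqrt(sum(weights * (values - mu)^2))
    iqrw <- diff(.weightedQuantile(values, weights, c(0.25, 0.75)))
    spread <- min(sdw, iqrw / 1.34)
    if (spread <= 0) spread <- max(abs(mu), 1) * 1e-6
    bandwidth <- 0.9 * spread * neff^(-1 / 5)
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(grid))
    grid <- seq(min(values) - 4 * bandwidth, max(values) + 4 * bandwidth,
                length.out = 512)
  dens <- vapply(grid,
                 function(x) sum(weights * stats::dnorm(x, values, bandwidth)),
                 numeric(1))
  list(grid = grid, density = dens, bandwidth = bandwidth)
}

.weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}

#' Split-half uncertainty of an ensemble metric
#'
#' Evaluates \code{metric} on the first and second halves of the frames (in
#' frame order, mirroring trajectory-half error bars) and returns the
#' standard deviation of the two values, |a - b| / sqrt(2).
#'
#' @param metric function taking a \linkS4class{ConformerEnsemble} and
#'   returning a scalar.
#' @param ensemble a \linkS4class{ConformerEnsemble} with >= 2 frames.
#' @return list with \code{sd}, \code{halves} (the two metric values).
#' @export
halfSplitUncertainty <- function(metric, ensemble) {
  n <- nFrames(ensemble)
  if (n < 2) stop("need at least 2 frames")
  h <- n %/% 2
  take <- function(sel) {
    w <- ensemble@weights[sel]
    new("ConformerEnsemble", atoms = ensemble@atoms,
        coords = ensemble@coords[, , sel, drop = FALSE],
        weights = w / sum(w), metadata = ensemble@metadata)
  }
  a <- metric(take(seq_len(h)))
  b <- metric(take((h + 1):n))
  list(sd = abs(a - b) / sqrt(2), halves = c(a, b))
}

#' Secondary-structure class from backbone dihedrals
#'
#' Region-based classifier on the Ramachandran plane (synthetic backbone
#' ensembles lack the hydrogen-bond geometry a DSSP-style assignment needs):
#' helix for phi in (-100, -30) and psi in (-77, -7); strand for phi in
#' (-180, -90) with psi in (90, 180] or psi in (-180, -170); coil otherwise.
#'
#' @param phi,psi dihedrals in degrees, in (-180, 180].
#' @return character vector: \code{"helix"}, \code{"strand"} or
#'   \code{"coil"}.
#' @export
ssClassify <- function(phi, psi) {
  stopifnot(length(phi) == length(psi))
  helix <- phi > -100 & phi < -30 & psi > -77 & psi < -7
  strand <- phi > -180 & phi < -90 &
    ((psi > 90 & psi <= 180) | (psi > -180 & psi < -170))
  out <- rep("coil", length(phi))
  out[strand] <- "strand"
  out[helix] <- "helix"
  out
}

#' Per-residue secondary-structure populations of an ensemble
#'
#' Weight-averaged fractions of helix, strand and coil per residue, using
#' \code{\link{ssClassify}} on the measured (phi, psi) of every frame.
#' Terminal residues lacking phi or psi are excluded and reported.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param weights optional frame weights (default prior weights).
#' @return data.frame with columns \code{resid}, \code{resname},
#'   \code{coil}, \code{helix}, \code{strand} (fractions summing to 1);
#'   attribute \code{"excluded"} lists residues without both angles.
#' @export
ssPopulations <- function(ensemble, weights = NULL) {
  if (is.null(weights)) weights <- ensemble@weights
  weights <- weights / sum(weights)
  n <- nFrames(ensemble)
  nres <- length(unique(ensemble@atoms$resid))
  counts <- matrix(0, nres, 3,
                   dimnames = list(NULL, c("coil", "helix", "strand")))
  for (k in seq_len(n)) {
    bd <- backboneDihedrals(getConformer(ensemble, k))
    ok <- !is.na(bd$phi) & !is.na(bd$psi)
    cls <- ssClassify(bd$phi[ok], bd$psi[ok])
    counts[cbind(which(ok), match(cls, colnames(counts)))] <-
      counts[cbind(which(ok), match(cls, colnames(counts)))] + weights[k]
  }
  excluded <- which(rowSums(counts) == 0)
  keep <- setdiff(seq_len(nres), excluded)
  out <- data.frame(resid = keep,
                    resname = ensemble@atoms$resname[
                      !duplicated(ensemble@atoms$resid)][keep],
                    coil = counts[keep, "coil"],
                    helix = counts[keep, "helix"],
                    strand = counts[keep, "strand"])
  out[, c("coil", "helix", "strand")] <-
    out[, c("coil", "helix", "strand")] / rowSums(counts[keep, , drop = FALSE])
  attr(out, "excluded") <- excluded
  out
}

#' Cis/trans subensemble summary
#'
#' Convenience wrapper producing the per-isomer summaries used to compare
#' proline subensembles: populations with split-half uncertainties, weighted
#' mean Rg with split-half uncertainties, weighted Rg KDEs on a common grid,
#' and CA contact maps.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param prolineResid proline residue index.
#' @param cutoff contact-map cutoff in nm.
#' @return list keyed by isomer with fields \code{population},
#'   \code{populationSD}, \code{meanRg}, \code{meanRgSD}, \code{kde},
#'   \code{contactMap}; plus \code{populations} for the full split.
#' @export
subensembleSummary <- function(ensemble, prolineResid, cutoff = 0.8) {
  sp <- splitByIsomer(ensemble, prolineResid)
  rgAll <- cvSeries(ensemble, "rg")$values
  grid <- seq(min(rgAll) - 0.5, max(rgAll) + 0.5, length.out = 512)
  popMetric <- function(which) function(e) {
    s <- splitByIsomer(e, prolineResid)
    unname(s$populations[which])
  }
  rgMetric <- function(e) sum(priorWeights(e) * cvSeries(e, "rg")$values)
  out <- list(populations = sp$populations)
  for (iso in c("cis", "trans")) {
    sub <- sp[[iso]]
    if (is.null(sub)) {
      out[[iso]] <- list(population = unname(sp$populations[iso]))
      next
    }
    w <- priorWeights(sub)
    rg <- cvSeries(sub, "rg")$values
    out[[iso]] <- list(
      population = unname(sp$populations[iso]),
      populationSD = halfSplitUncertainty(popMetric(iso), ensemble)$sd,
      meanRg = sum(w * rg),
      meanRgSD = if (nFrames(sub) >= 2)
        halfSplitUncertainty(rgMetric, sub)$sd else NA_real_,
      kde = weightedKDE(rg, w, grid = grid),
      contactMap = caContactMap(sub, cutoff = cutoff))
  }
  out
}
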