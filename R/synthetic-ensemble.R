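#' Generator configuration for synthetic disordered-peptide ensembles
#'
#' Parameters of the desk-scale conformer generator that stands in for
#' long enhanced-sampling trajectories.  The default sequence is the
#' 21-residue C-terminal region of the SARS-CoV-2 ORF6 protein
#' (SKSLTENKYSQLDEEQPMEID) with its single proline at construct position 17
#' (position 57 in full-length numbering).
#'
#' Backbone (phi, psi) pairs are drawn per residue from a three-basin
#' mixture (PPII, beta, alpha-R) emulating coil-library sampling of a
#' disordered chain; the proline phi is fixed at -65 degrees.  The omega
#' torsion at the proline peptide bond is drawn near 0 with probability
#' \code{cisFraction} and near 180 otherwise; all other peptide bonds are
#' trans.  Self-clashing frames are rejected, and an optional compaction
#' bias accepts frames with probability min(1, (rgRef/Rg)^compaction).
#'
#' @param sequence one-letter peptide sequence (>= 2 residues).
#' @param prolinePosition 1-based position of the proline of interest;
#'   default: the first proline in \code{sequence}.
#' @param nConformers number of frames to generate.
#' @param cisFraction probability of the cis isomer at the proline, in
#'   [0, 1].  Default 0.10, a typical cis-proline population in disordered
#'   proteins.
#' @param basinProbs named probabilities for the (phi, psi) basins
#'   (\code{ppii}, \code{beta}, \code{alphaR}), summing to 1.
#' @param basinCenters 3 x 2 matrix of basin centres (phi, psi) in degrees.
#' @param angularSD standard deviation (degrees) around basin centres.
#' @param omegaSD standard deviation (degrees) around the ideal 0/180
#'   peptide-bond torsions (default 8, a narrow planarity spread).
#' @param prolinePhi fixed proline phi (degrees).
#' @param compaction acceptance-bias exponent c >= 0 on Rg (0 = no bias).
#' @param rgRef reference Rg (nm) for the compaction bias.
#' @param compactIsomer which frames the compaction bias applies to:
#'   \code{"both"}, \code{"cis"} or \code{"trans"}.
#' @param clashDistance minimum allowed distance (nm) between atoms three
#'   or more bonds apart.
#' @param seed integer random seed, recorded in the ensemble metadata.
#' @return A validated list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(sequence = "SKSLTENKYSQLDEEQPMEID",
                            prolinePosition = NULL,
                            nConformers = 100L,
                            cisFraction = 0.10,
                            basinProbs = c(ppii = 0.45, beta = 0.35,
                                           alphaR = 0.20),
                            basinCenters = rbind(ppii = c(-75, 150),
                                                 beta = c(-120, 130),
                                                 alphaR = c(-60, -45)),
                            angularSD = 15,
                            omegaSD = 8,
                            prolinePhi = -65,
                            compaction = 0,
                            rgRef = 1.0,
                            compactIsomer = c("both", "cis", "trans"),
                            clashDistance = 0.25,
                            seed = 1L) {
  compactIsomer <- match.arg(compactIsomer)
  seqv <- strsplit(sequence, "")[[1]]
  if (is.null(prolinePosition)) {
    prolinePosition <- which(seqv == "P")[1]
    if (is.na(prolinePosition)) prolinePosition <- NA_integer_
  }
  if (!is.na(prolinePosition) && seqv[prolinePosition] != "P")
    stop(sprintf("residue %d of the sequence is not a proline", prolinePosition))
  if (abs(sum(basinProbs) - 1) > 1e-12)
    stop("basin probabilities must sum to 1 (tolerance 1e-12)")
  stopifnot(nConformers >= 1, cisFraction >= 0, cisFraction <= 1,
            angularSD > 0, omegaSD > 0, compaction >= 0, rgRef > 0,
            clashDistance >= 0, nrow(basinCenters) == length(basinProbs))
  cfg <- list(sequence = sequence, prolinePosition = prolinePosition,
              nConformers = as.integer(nConformers),
              cisFraction = cisFraction, basinProbs = basinProbs,
              basinCenters = basinCenters, angularSD = angularSD,
              omegaSD = omegaSD, prolinePhi = prolinePhi,
              compaction = compaction, rgRef = rgRef,
              compactIsomer = compactIsomer,
              clashDistance = clashDistance, seed = as.integer(seed))
  class(cfg) <- "generatorConfig"
  cfg
}

.configHash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 4294967291)
}

# bond-path distances between atoms of a backbone topology (BFS), used to
# exclude bonded and angle-connected pairs from the clash check
.bondSeparation <- function(atoms) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  addBond <- function(i, j) {
    adj[[i]] <<- c(adj[[i]], j)
    adj[[j]] <<- c(adj[[j]], i)
  }
  for (r in unique(atoms$resid)) {
    iN <- .atomIndex(atoms, r, "N")
    iCA <- .atomIndex(atoms, r, "CA")
    iC <- .atomIndex(atoms, r, "C")
    iO <- .atomIndex(atoms, r, "O")
    addBond(iN, iCA); addBond(iCA, iC); addBond(iC, iO)
    if (atoms$resname[match(r, atoms$resid)] == "PRO")
      addBond(iN, .atomIndex(atoms, r, "CD"))
    if (r > min(atoms$resid))
      addBond(.atomIndex(atoms, r - 1, "C"), iN)
  }
  sep <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (dist[v] > dist[u] + 1) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
    sep[s, ] <- dist
  }
  sep
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Sample a synthetic conformer ensemble
#'
#' Generates \code{nConformers} independent frames under the model described
#' in \code{\link{generatorConfig}} by rejection sampling: draw dihedrals,
#' rebuild Cartesian coordinates with \code{\link{buildBackbone}}, reject
#' self-clashing frames, and (optionally) bias acceptance towards compact
#' frames.  Identical config + seed gives bit-identical output.  Weights are
#' uniform; see \code{\link{attachWeights}} for bias-derived weights.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return A \linkS4class{ConformerEnsemble} with uniform prior weights and
#'   metadata fields \code{seed}, \code{configHash}, \code{config} and
#'   \code{isomer} (the drawn per-frame isomer label at the proline).
#' @export
sampleEnsemble <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  seqv <- strsplit(config$sequence, "")[[1]]
  n <- length(seqv)
  pPos <- config$prolinePosition
  nb <- length(config$basinProbs)

  layout <- .chainLayout(.seqTo3letter(config$sequence))
  geometry <- backboneGeometry()
  atoms <- layout$atoms
  natoms <- nrow(atoms)
  masses <- atoms$mass
  sep <- .bondSeparation(atoms)
  # mask over dist() ordering: pairs (i<j) three or more bonds apart
  pairI <- rep(seq_len(natoms - 1), times = (natoms - 1):1)
  pairJ <- unlist(lapply(seq_len(natoms - 1), function(i) (i + 1):natoms))
  clashMask <- sep[cbind(pairI, pairJ)] >= 3

  coords <- array(NA_real_, c(natoms, 3, config$nConformers))
  isomer <- character(config$nConformers)
  .withSeed(config$seed, {
    attempts <- 0L
    for (frame in seq_len(config$nConformers)) {
      # the isomer label is drawn once per frame; the conformation is then
      # rejection-sampled conditional on it, so the realized cis fraction
      # stays binomial at cisFraction regardless of isomer-dependent
      # clash/compaction acceptance rates
      iso <- if (!is.na(pPos) && stats::runif(1) < config$cisFraction)
        "cis" else "trans"
      repeat {
        attempts <- attempts + 1L
        if (attempts >= 1e5 && (frame - 1) / attempts < 0.01)
          stop(sprintf(paste0("rejection rate above 99%% (%d accepted in %d ",
                              "attempts); loosen clashDistance or compaction"),
                       frame - 1L, attempts))
        basin <- sample.int(nb, n, replace = TRUE, prob = config$basinProbs)
        phi <- config$basinCenters[basin, 1] +
          stats::rnorm(n, 0, config$angularSD)
        psi <- config$basinCenters[basin, 2] +
          stats::rnorm(n, 0, config$angularSD)
        omega <- 180 + stats::rnorm(n, 0, config$omegaSD)
        if (!is.na(pPos)) {
          phi[pPos] <- config$prolinePhi
          if (iso == "cis") omega[pPos] <- stats::rnorm(1, 0, config$omegaSD)
        }
        xyz <- .buildBackboneXYZ(layout, phi, psi, omega, geometry)
        d <- stats::dist(xyz)
        if (any(d[clashMask] < config$clashDistance)) next
        if (config$compaction > 0 &&
            (config$compactIsomer == "both" || config$compactIsomer == iso)) {
          rg <- .rgFromXYZ(xyz, masses)
          if (stats::runif(1) > min(1, (config$rgRef / rg)^config$compaction))
            next
        }
        break
      }
      coords[, , frame] <- xyz
      isomer[frame] <- iso
    }
  })
  new("ConformerEnsemble", atoms = atoms, coords = coords,
      weights = rep(1 / config$nConformers, config$nConformers),
      metadata = list(seed = config$seed, configHash = .configHash(config),
                      config = config, isomer = isomer))
}

#' Attach statistical weights to an ensemble
#'
#' \code{mode = "uniform"} sets w_i = 1/n.  \code{mode = "from_bias"}
#' implements the final-bias estimator used for well-tempered metadynamics:
#' w_i proportional to exp(V_i / (kB T)) with V the bias potential (kJ/mol)
#' evaluated at the end of the run, normalized over frames.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param mode \code{"uniform"} or \code{"from_bias"}.
#' @param bias numeric vector of final-bias values in kJ/mol, one per frame
#'   (required for \code{"from_bias"}).
#' @param temperature temperature in kelvin (default 310).
#' @return The ensemble with updated prior weights.
#' @export
attachWeights <- function(ensemble, mode = c("uniform", "from_bias"),
                          bias = NULL, temperature = 310) {
  mode <- match.arg(mode)
  n <- nFrames(ensemble)
  if (mode == "uniform") {
    w <- rep(1 / n, n)
  } else {
    if (is.null(bias) || length(bias) != n)
      stop("from_bias mode requires one bias value per frame")
    if (any(!is.finite(bias))) stop("bias values must be finite")
    kB <- 0.0083144621  # kJ mol^-1 K^-1
    e <- bias / (kB * temperature)
    w <- exp(e - max(e))
    w <- w / sum(w)
  }
  ensemble@weights <- w
  validObject(ensemble)
  ensemble
}
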