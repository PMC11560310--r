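#' Classify a peptide-bond torsion as cis or trans
#'
#' Cis if the absolute omega torsion is below 90 degrees, trans otherwise
#' (the 90-degree boundary is assigned trans).  The boundary sits midway
#' between the ideal cis (0) and trans (180) geometries, which cleanly
#' separates the two narrow peptide-bond planarity basins.
#'
#' @param omega numeric vector of torsions in degrees.
#' @return character vector, \code{"cis"} or \code{"trans"}.
#' @export
classifyIsomer <- function(omega) {
  stopifnot(all(is.finite(omega)))
  ifelse(abs(omega) < 90, "cis", "trans")
}

.caMatrix <- function(atoms) which(atoms$name == "CA")

#' Radius of gyration
#'
#' sqrt(sum m_i |r_i - r_com|^2 / sum m_i) over the atoms of one conformer;
#' with \code{massWeighted = FALSE} all masses are taken as 1.  Note that
#' backbone-only synthetic conformers give systematically different absolute
#' Rg values than all-atom structures of the same chain.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param massWeighted logical, default TRUE.
#' @return Rg in nm.
#' @export
radiusOfGyration <- function(conformer, massWeighted = TRUE) {
  x <- conformer@coords
  m <- if (massWeighted) conformer@atoms$mass else rep(1, nrow(x))
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

.rgFromXYZ <- function(x, m = NULL) {
  if (is.null(m)) m <- rep(1, nrow(x))
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' End-to-end distance
#'
#' Euclidean distance between the CA atoms of the first and last residue.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @return distance in nm.
#' @export
endToEnd <- function(conformer) {
  atoms <- conformer@atoms
  rr <- range(atoms$resid)
  a <- conformer@coords[.atomIndex(atoms, rr[1], "CA"), ]
  b <- conformer@coords[.atomIndex(atoms, rr[2], "CA"), ]
  sqrt(sum((a - b)^2))
}

#' Dihedral correlation between consecutive psi angles
#'
#' sum over consecutive psi pairs of (1 + cos(psi_i - psi_{i+1})) / 2.
#' With n residues there are n - 1 measurable psi angles and n - 2 pairs;
#' the value lies in [0, n_pairs].
#'
#' @param conformer a \linkS4class{Conformer} with >= 3 residues.
#' @return dimensionless scalar.
#' @export
dihedralCorrelation <- function(conformer) {
  psi <- backboneDihedrals(conformer)$psi
  psi <- psi[!is.na(psi)]
  if (length(psi) < 2)
    stop("dihedral correlation needs at least 3 residues")
  d <- diff(.deg2rad(psi))
  sum((1 + cos(d)) / 2)
}

#' Ensemble-averaged CA contact-probability map
#'
#' Entry (i, j) is the weighted fraction of frames in which the CA atoms of
#' residues i and j are closer than \code{cutoff}; the diagonal is 1 and the
#' matrix is symmetric.  The default cutoff of 0.8 nm is a common CA contact
#' threshold (configurable).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param cutoff contact distance in nm, > 0.
#' @param weights optional frame weights (default: the ensemble's prior
#'   weights), normalized.
#' @return residue x residue numeric matrix of contact probabilities.
#' @export
caContactMap <- function(ensemble, cutoff = 0.8, weights = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(weights)) weights <- ensemble@weights
  stopifnot(length(weights) == nFrames(ensemble))
  weights <- weights / sum(weights)
  ca <- .caMatrix(ensemble@atoms)
  nres <- length(ca)
  cmap <- matrix(0, nres, nres)
  for (k in seq_len(nFrames(ensemble))) {
    x <- ensemble@coords[ca, , k]
    d <- as.matrix(stats::dist(x))
    cmap <- cmap + weights[k] * (d < cutoff)
  }
  diag(cmap) <- 1
  dimnames(cmap) <- NULL
  (cmap + t(cmap)) / 2
}

#' Per-frame collective-variable series
#'
#' Extracts one value per frame for a named collective variable:
#' \code{"rg"} (mass-weighted radius of gyration, nm), \code{"end_to_end"}
#' (nm), \code{"dihcor"} (dihedral correlation, dimensionless),
#' \code{"psi:<res>"} or \code{"zeta:<res>"} (degrees, 1-based residue
#' index; zeta requires a proline).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param cv character CV name.
#' @return list with \code{name}, \code{values} (one per frame) and
#'   \code{units}.
#' @export
cvSeries <- function(ensemble, cv) {
  stopifnot(is.character(cv), length(cv) == 1L)
  n <- nFrames(ensemble)
  frameFun <- NULL
  units <- ""
  if (cv == "rg") {
    frameFun <- function(co) radiusOfGyration(co)
    units <- "nm"
  } else if (cv == "end_to_end") {
    frameFun <- endToEnd
    units <- "nm"
  } else if (cv == "dihcor") {
    frameFun <- dihedralCorrelation
    units <- "dimensionless"
  } else if (grepl("^psi:[0-9]+$", cv)) {
    r <- as.integer(sub("^psi:", "", cv))
    atoms <- ensemble@atoms
    nres <- length(unique(atoms$resid))
    if (r < 1 || r >= nres)
      stop(sprintf("psi is defined for residues 1..%d", nres - 1L))
    ii <- c(.atomIndex(atoms, r, "N"), .atomIndex(atoms, r, "CA"),
            .atomIndex(atoms, r, "C"), .atomIndex(atoms, r + 1, "N"))
    frameFun <- function(co) measureDihedral(co, ii)
    units <- "degrees"
  } else if (grepl("^zeta:[0-9]+$", cv)) {
    r <- as.integer(sub("^zeta:", "", cv))
    atoms <- ensemble@atoms
    if (atoms$resname[match(r, atoms$resid)] != "PRO")
      stop(sprintf("zeta requested on residue %d, which is not a proline", r))
    frameFun <- function(co) zetaAngle(co, r)
    units <- "degrees"
  } else {
    stop("unknown CV: ", cv,
         " (expected rg, end_to_end, dihcor, psi:<res> or zeta:<res>)")
  }
  vals <- vapply(seq_len(n), function(k) frameFun(getConformer(ensemble, k)),
                 numeric(1))
  list(name = cv, values = vals, units = units)
}

#' Per-frame omega torsion at a peptide bond
#'
#' Convenience extractor of the omega torsion preceding \code{resid} for
#' every frame of an ensemble (the quantity classified by
#' \code{\link{classifyIsomer}}).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param resid residue whose preceding peptide bond is measured (>= 2).
#' @return numeric vector of torsions in degrees, one per frame.
#' @export
omegaSeries <- function(ensemble, resid) {
  atoms <- ensemble@atoms
  if (resid < 2) stop("omega requires a preceding residue")
  ii <- c(.atomIndex(atoms, resid - 1, "CA"), .atomIndex(atoms, resid - 1, "C"),
          .atomIndex(atoms, resid, "N"), .atomIndex(atoms, resid, "CA"))
  vapply(seq_len(nFrames(ensemble)),
         function(k) measureDihedral(getConformer(ensemble, k), ii),
         numeric(1))
}
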