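#' @import methods
NULL

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

.checkAtomTable <- function(atoms) {
  required <- c("name", "resid", "resname", "element", "mass")
  if (!all(required %in% names(atoms)))
    return(sprintf("atom table must have columns: %s",
                   paste(required, collapse = ", ")))
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    return("atom masses must be finite and > 0")
  for (r in unique(atoms$resid)) {
    nm <- atoms$name[atoms$resid == r]
    if (!all(.BACKBONE_NAMES %in% nm))
      return(sprintf("residue %d lacks a full backbone (N, CA, C, O)", r))
    if (atoms$resname[atoms$resid == r][1] == "PRO" && !("CD" %in% nm))
      return(sprintf("proline residue %d lacks its CD atom", r))
  }
  TRUE
}

#' Conformer: a single structural frame
#'
#' Holds one conformation of a peptide chain as an atom metadata table plus a
#' Cartesian coordinate matrix in nanometres.  Every residue must carry a full
#' backbone (N, CA, C, O) and every proline additionally its CD atom, which is
#' required for the zeta improper dihedral used to monitor cis/trans
#' isomerization.
#'
#' @slot atoms data.frame with columns \code{name} (PDB atom name),
#'   \code{resid} (1-based residue index), \code{resname} (3-letter code),
#'   \code{element}, \code{mass} (Da).
#' @slot coords numeric matrix, one row per atom, columns x/y/z in nm.
#' @exportClass Conformer
setClass("Conformer",
         representation(atoms = "data.frame", coords = "matrix"),
         validity = function(object) {
           msg <- .checkAtomTable(object@atoms)
           if (!isTRUE(msg)) return(msg)
           if (nrow(object@coords) != nrow(object@atoms))
             return("coordinate rows must match atom table rows")
           if (ncol(object@coords) != 3L)
             return("coordinates must have 3 columns (x, y, z)")
           if (any(!is.finite(object@coords)))
             return("coordinates must be finite")
           TRUE
         })

#' ConformerEnsemble: an ordered set of conformers with prior weights
#'
#' The central container consumed by every analysis stage: an ordered set of
#' conformers sharing one atom table, a per-frame statistical weight vector
#' (normalized to 1), and provenance metadata (generator config, seed).
#' For metadynamics-derived ensembles the weights are the final-bias
#' statistical weights; synthetic ensembles default to uniform weights.
#'
#' @slot atoms shared atom metadata table (see \linkS4class{Conformer}).
#' @slot coords numeric array \code{[n_atoms, 3, n_frames]} in nm.
#' @slot weights numeric vector of per-frame prior weights, >= 0, summing to 1.
#' @slot metadata list of provenance fields (seed, config hash, ...).
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble",
         representation(atoms = "data.frame", coords = "array",
                        weights = "numeric", metadata = "list"),
         validity = function(object) {
           msg <- .checkAtomTable(object@atoms)
           if (!isTRUE(msg)) return(msg)
           d <- dim(object@coords)
           if (length(d) != 3L || d[1] != nrow(object@atoms) || d[2] != 3L)
             return("coords must be an [n_atoms, 3, n_frames] array")
           if (length(object@weights) != d[3])
             return("one weight per frame required")
           if (any(object@weights < 0))
             return("weights must be non-negative")
           if (abs(sum(object@weights) - 1) > 1e-12)
             return("weights must sum to 1 (tolerance 1e-12)")
           if (any(!is.finite(object@coords)))
             return("coordinates must be finite")
           TRUE
         })

#' SAXSProfile: a small-angle X-ray scattering intensity curve
#'
#' Scattering vector magnitudes q (nm^-1, strictly increasing; q = 0 allowed
#' as the first point), intensities I (arbitrary units) and optional
#' uncertainties sigma.  \code{errorScale} carries the error-bar rescaling
#' factor estimated externally (e.g. by a Bayesian indirect Fourier
#' transform); it multiplies sigma wherever the profile is used in fits.
#'
#' @slot q numeric, nm^-1.
#' @slot I numeric intensities.
#' @slot sigma numeric uncertainties (NA when absent).
#' @slot errorScale single positive number, default 1.
#' @exportClass SAXSProfile
setClass("SAXSProfile",
         representation(q = "numeric", I = "numeric", sigma = "numeric",
                        errorScale = "numeric"),
         prototype(errorScale = 1),
         validity = function(object) {
           if (length(object@q) != length(object@I))
             return("q and I must have the same length")
           if (length(object@sigma) != length(object@q))
             return("sigma must have the same length as q (use NA if absent)")
           if (any(object@q < 0)) return("q must be >= 0")
           if (any(diff(object@q) <= 0)) return("q must be strictly increasing")
           if (any(!is.na(object@sigma) & object@sigma <= 0))
             return("sigma must be > 0 where present")
           if (length(object@errorScale) != 1 || object@errorScale <= 0)
             return("errorScale must be a single positive number")
           TRUE
         })

#' RestraintSet: experimental restraints with per-frame calculated observables
#'
#' Couples experimental values \code{observed} (with uncertainties
#' \code{sigma}) to the matrix \code{calc} of the same observables computed
#' for every frame of an ensemble (rows = frames, columns = restraints).
#' This is the input of BME reweighting.
#'
#' @slot labels character restraint labels.
#' @slot observed numeric experimental values o_j.
#' @slot sigma numeric uncertainties sigma_j > 0.
#' @slot calc numeric matrix F[i, j], frame i, restraint j.
#' @exportClass RestraintSet
setClass("RestraintSet",
         representation(labels = "character", observed = "numeric",
                        sigma = "numeric", calc = "matrix"),
         validity = function(object) {
           m <- length(object@observed)
           if (length(object@labels) != m || length(object@sigma) != m)
             return("labels, observed and sigma must have equal length")
           if (ncol(object@calc) != m)
             return("calc must have one column per restraint")
           if (any(object@sigma <= 0)) return("sigma must be > 0")
           if (any(!is.finite(object@calc)))
             return("calculated observables must be finite")
           TRUE
         })

#' BMEResult: posterior of a Bayesian/maximum-entropy reweighting
#'
#' Posterior frame weights and diagnostics of \code{\link{fitBME}}:
#' Lagrange multipliers lambda (one per restraint), reduced chi-squared
#' before/after, the relative entropy S_rel = -sum w log(w/w0) and the
#' effective retained ensemble fraction phi_eff = exp(S_rel), plus the
#' confidence parameter theta used.
#'
#' @slot lambda numeric Lagrange multipliers.
#' @slot weights numeric posterior weights (normalized).
#' @slot priorWeights numeric prior weights.
#' @slot chi2Prior,chi2Posterior single numbers, total chi-squared.
#' @slot sRel relative entropy (<= 0).
#' @slot phiEff effective sample fraction in (0, 1].
#' @slot theta confidence parameter.
#' @slot converged logical; \code{gradNorm} final gradient norm.
#' @slot gradNorm numeric.
#' @exportClass BMEResult
setClass("BMEResult",
         representation(lambda = "numeric", weights = "numeric",
                        priorWeights = "numeric",
                        chi2Prior = "numeric", chi2Posterior = "numeric",
                        sRel = "numeric", phiEff = "numeric",
                        theta = "numeric", converged = "logical",
                        gradNorm = "numeric"),
         validity = function(object) {
           if (any(object@weights < 0)) return("posterior weights must be >= 0")
           if (abs(sum(object@weights) - 1) > 1e-12)
             return("posterior weights must sum to 1")
           if (object@phiEff <= 0 || object@phiEff > 1 + 1e-12)
             return("phiEff must lie in (0, 1]")
           TRUE
         })
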