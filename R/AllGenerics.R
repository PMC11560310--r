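#' Accessors for ensemble and conformer objects
#'
#' \code{nFrames} returns the number of conformers in an ensemble;
#' \code{priorWeights} the per-frame statistical weights;
#' \code{atomTable} the shared atom metadata; \code{atomCoords} the raw
#' coordinates (nm); \code{getConformer} extracts one frame as a
#' \linkS4class{Conformer}; \code{peptideSequence} the 3-letter residue codes.
#'
#' @param x a \linkS4class{ConformerEnsemble} or \linkS4class{Conformer}.
#' @param i frame index (1-based).
#' @param value replacement weights (will be checked for normalization).
#' @return See individual descriptions.
#' @name ensemble-accessors
#' @aliases nFrames priorWeights priorWeights<- atomTable atomCoords
#'   getConformer peptideSequence
NULL

#' @rdname ensemble-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ensemble-accessors
#' @export
setGeneric("priorWeights", function(x) standardGeneric("priorWeights"))

#' @rdname ensemble-accessors
#' @export
setGeneric("priorWeights<-", function(x, value) standardGeneric("priorWeights<-"))

#' @rdname ensemble-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ensemble-accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname ensemble-accessors
#' @export
setGeneric("getConformer", function(x, i) standardGeneric("getConformer"))

#' @rdname ensemble-accessors
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @rdname ensemble-accessors
#' @export
setMethod("nFrames", "ConformerEnsemble", function(x) dim(x@coords)[3])

#' @rdname ensemble-accessors
#' @export
setMethod("priorWeights", "ConformerEnsemble", function(x) x@weights)

#' @rdname ensemble-accessors
#' @export
setMethod("priorWeights<-", "ConformerEnsemble", function(x, value) {
  x@weights <- value
  validObject(x)
  x
})

#' @rdname ensemble-accessors
#' @export
setMethod("atomTable", "ConformerEnsemble", function(x) x@atoms)

#' @rdname ensemble-accessors
#' @export
setMethod("atomTable", "Conformer", function(x) x@atoms)

#' @rdname ensemble-accessors
#' @export
setMethod("atomCoords", "ConformerEnsemble", function(x) x@coords)

#' @rdname ensemble-accessors
#' @export
setMethod("atomCoords", "Conformer", function(x) x@coords)

#' @rdname ensemble-accessors
#' @export
setMethod("getConformer", "ConformerEnsemble", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  new("Conformer", atoms = x@atoms, coords = x@coords[, , i, drop = TRUE])
})

#' @rdname ensemble-accessors
#' @export
setMethod("peptideSequence", "Conformer", function(x) {
  x@atoms$resname[!duplicated(x@atoms$resid)]
})

#' @rdname ensemble-accessors
#' @export
setMethod("peptideSequence", "ConformerEnsemble", function(x) {
  x@atoms$resname[!duplicated(x@atoms$resid)]
})

setMethod("show", "Conformer", function(object) {
  cat(sprintf("Conformer: %d residues, %d atoms\n",
              length(unique(object@atoms$resid)), nrow(object@atoms)))
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d frames, %d residues, %d atoms/frame\n",
              nFrames(object), length(unique(object@atoms$resid)),
              nrow(object@atoms)))
  w <- object@weights
  cat(sprintf("  weights: min %.3g, max %.3g, effective frames %.1f\n",
              min(w), max(w), 1 / sum(w^2)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "SAXSProfile", function(object) {
  cat(sprintf("SAXSProfile: %d points, q in [%.4g, %.4g] nm^-1%s\n",
              length(object@q), min(object@q), max(object@q),
              if (all(is.na(object@sigma))) ", no uncertainties" else ""))
  if (object@errorScale != 1)
    cat(sprintf("  error-rescale factor: %.4g\n", object@errorScale))
})

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet: %d restraints x %d frames\n",
              length(object@observed), nrow(object@calc)))
})

setMethod("show", "BMEResult", function(object) {
  cat("BMEResult\n")
  cat(sprintf("  theta: %.4g,  converged: %s (|grad| = %.2e)\n",
              object@theta, object@converged, object@gradNorm))
  cat(sprintf("  chi2: %.4g (prior) -> %.4g (posterior)\n",
              object@chi2Prior, object@chi2Posterior))
  cat(sprintf("  phi_eff: %.4g\n", object@phiEff))
})
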