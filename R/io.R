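#' Write an ensemble as multi-model PDB plus a weight file
#'
#' Coordinates are converted from nm to Angstrom and written as
#' MODEL/ENDMDL blocks via bio3d; weights go to a companion plain-text
#' file, one per line, with a comment header recording seed and config
#' hash.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param pdbPath output PDB path.
#' @param weightsPath optional weight-file path (skipped when NULL).
#' @return invisibly, the PDB path.
#' @export
writeEnsemble <- function(ensemble, pdbPath, weightsPath = NULL) {
  atoms <- ensemble@atoms
  n <- nFrames(ensemble)
  xyz <- t(vapply(seq_len(n),
                  function(k) as.numeric(t(ensemble@coords[, , k])) * 10,
                  numeric(3 * nrow(atoms))))
  bio3d::write.pdb(file = pdbPath, xyz = xyz,
                   resno = atoms$resid, resid = atoms$resname,
                   elety = atoms$name)
  if (!is.null(weightsPath))
    writeWeights(ensemble@weights, weightsPath,
                 header = sprintf("seed=%s configHash=%s",
                                  ensemble@metadata$seed %||% "NA",
                                  ensemble@metadata$configHash %||% "NA"))
  invisible(pdbPath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ensemble from multi-model PDB (and optional weights)
#'
#' Parses MODEL/ENDMDL blocks with bio3d, converts Angstrom to nm, and
#' checks that the atom layout is identical across models.  Missing
#' weights give a uniform prior; a weight file with the wrong number of
#' entries is a hard error.
#'
#' @param pdbPath multi-model PDB path.
#' @param weightsPath optional weight file (one weight per line, '#'
#'   comments allowed).
#' @return A \linkS4class{ConformerEnsemble}.
#' @export
readEnsemble <- function(pdbPath, weightsPath = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(pdbPath, multi = TRUE),
                  error = function(e)
                    stop("failed to parse multi-model PDB (", pdbPath,
                         "): ", conditionMessage(e)))
  natoms <- nrow(pdb$atom)
  nmodels <- nrow(pdb$xyz)
  if (ncol(pdb$xyz) != 3 * natoms)
    stop(sprintf("inconsistent atom counts across models in %s", pdbPath))
  el <- substr(pdb$atom$elety, 1, 1)
  if (!all(el %in% names(.ELEMENT_MASS)))
    stop("unknown element(s) in PDB atom names")
  atoms <- data.frame(name = pdb$atom$elety, resid = pdb$atom$resno,
                      resname = pdb$atom$resid, element = el,
                      mass = unname(.ELEMENT_MASS[el]),
                      stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(natoms, 3, nmodels))
  for (k in seq_len(nmodels))
    coords[, , k] <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE) / 10
  w <- if (is.null(weightsPath)) rep(1 / nmodels, nmodels)
       else readWeights(weightsPath)
  if (length(w) != nmodels)
    stop(sprintf("weight file has %d entries for %d models",
                 length(w), nmodels))
  w <- w / sum(w)
  new("ConformerEnsemble", atoms = atoms, coords = coords, weights = w,
      metadata = list(source = pdbPath))
}

#' Read / write per-frame weight files
#'
#' Plain text, one weight per line; lines starting with '#' are comments.
#' Weights are normalized on read.
#'
#' @param path file path.
#' @param weights numeric weights.
#' @param header optional comment header text (without the leading '#').
#' @return \code{readWeights}: numeric vector (normalized).
#' @export
readWeights <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  w <- suppressWarnings(as.numeric(lines))
  if (any(is.na(w))) stop("non-numeric entries in weight file ", path)
  if (any(w < 0)) stop("negative weights in ", path)
  w / sum(w)
}

#' @rdname readWeights
#' @export
writeWeights <- function(weights, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%.12g", weights), con)
  invisible(path)
}

#' Read / write SAXS profiles as 2-3 column text
#'
#' Whitespace- or comma-separated columns q, I and optional sigma; lines
#' starting with '#' are skipped.  q is converted to nm^-1
#' (\code{unit = "angstrom"} multiplies by 10).
#'
#' @param path file path.
#' @param unit q unit in the file: \code{"nm"} (nm^-1) or
#'   \code{"angstrom"} (A^-1).
#' @param errorScale error-bar rescaling factor to attach.
#' @return A \linkS4class{SAXSProfile}.
#' @export
readSAXS <- function(path, unit = c("nm", "angstrom"), errorScale = 1) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  ncols <- lengths(parts)
  if (any(ncols < 2)) stop("SAXS file needs at least 2 columns (q, I)")
  q <- as.numeric(vapply(parts, `[`, "", 1))
  I <- as.numeric(vapply(parts, `[`, "", 2))
  sigma <- if (all(ncols >= 3))
    as.numeric(vapply(parts, `[`, "", 3)) else rep(NA_real_, length(q))
  if (any(is.na(q)) || any(is.na(I))) stop("non-numeric q or I entries")
  if (unit == "angstrom") q <- q * 10
  if (is.unsorted(q, strictly = TRUE))
    stop("q must be strictly increasing")
  saxsProfile(q, I, sigma, errorScale = errorScale)
}

#' @rdname readSAXS
#' @param profile a \linkS4class{SAXSProfile} to write (q in nm^-1).
#' @export
writeSAXS <- function(profile, path) {
  df <- data.frame(q = profile@q, I = profile@I, sigma = profile@sigma)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q[nm^-1] I sigma", con)
  utils::write.table(format(df, digits = 12), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV table with a required schema
#'
#' Thin wrapper around \code{read.csv} that checks the required columns
#' are present, for the tabular NMR inputs (peak volumes, relaxation
#' decays, shift series).
#'
#' @param path CSV path.
#' @param columns character vector of required column names.
#' @return data.frame.
#' @export
readTableChecked <- function(path, columns) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop(sprintf("%s lacks required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

#' Save / load a run configuration as YAML
#'
#' Serializes the full parameter set of an analysis run (generator config,
#' cutoffs, theta grid, seeds, paths) so every output directory carries the
#' exact configuration that produced it.
#'
#' @param config named list of parameters.
#' @param path YAML path.
#' @return \code{loadRunConfig}: the named list.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  yaml::read_yaml(path)
}
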