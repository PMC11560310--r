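#' Default backbone geometry parameters
#'
#' Bond lengths (nm) and bond angles (degrees) used by
#' \code{\link{buildBackbone}} when extending a chain in internal
#' coordinates.  Defaults are canonical peptide values (Engh-Huber-like):
#' N-CA 0.1458 nm, CA-C 0.1525 nm, peptide C-N 0.1329 nm, C=O 0.1231 nm and
#' the proline N-CD bond 0.1473 nm; angles N-CA-C 111.0, CA-C-N 116.2,
#' C-N-CA 121.7, CA-C-O 120.8 and C-N-CD 125.0 degrees.
#'
#' @param lengths named numeric vector of bond lengths in nm
#'   (\code{nca}, \code{cac}, \code{cn}, \code{co}, \code{ncd}).
#' @param angles named numeric vector of bond angles in degrees
#'   (\code{ncac}, \code{cacn}, \code{cnca}, \code{caco}, \code{cncd}).
#' @return A list with components \code{lengths} and \code{angles}.
#' @export
backboneGeometry <- function(lengths = c(nca = 0.1458, cac = 0.1525,
                                         cn = 0.1329, co = 0.1231,
                                         ncd = 0.1473),
                             angles = c(ncac = 111.0, cacn = 116.2,
                                        cnca = 121.7, caco = 120.8,
                                        cncd = 125.0)) {
  stopifnot(all(lengths > 0),
            all(angles > 0 & angles < 180))
  list(lengths = lengths, angles = angles)
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (zero-length) bond vector")
  v / n
}

# NeRF placement: position of atom D bonded to C, given the torsion
# A-B-C-D (degrees), the bond angle B-C-D (degrees) and bond length C-D.
.placeAtom <- function(a, b, c_, bond, angle, torsion) {
  th <- .deg2rad(angle)
  chi <- .deg2rad(torsion)
  bc <- .unit(c_ - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Signed dihedral (torsion) angle of four points
#'
#' Standard IUPAC torsion: 0 degrees is syn/cis, +/-180 anti/trans, sign by
#' the right-hand rule.  The result is in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined torsion: collinear bond vectors")
  m1 <- .cross(.unit(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- .rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral by atom indices of a conformer
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param idx integer vector of four distinct atom indices in torsion order.
#' @return Signed torsion angle in degrees, range (-180, 180].
#' @seealso \code{\link{dihedralAngle}}, \code{\link{backboneDihedrals}}
#' @export
measureDihedral <- function(conformer, idx) {
  stopifnot(length(idx) == 4L, !anyDuplicated(idx),
            all(idx >= 1L), all(idx <= nrow(conformer@coords)))
  x <- conformer@coords
  dihedralAngle(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ])
}

.atomIndex <- function(atoms, resid, name) {
  i <- which(atoms$resid == resid & atoms$name == name)
  if (length(i) != 1L)
    stop(sprintf("atom %s of residue %d not found (or not unique)", name, resid))
  i
}

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
          Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.ELEMENT_MASS <- c(N = 14.007, C = 12.011, O = 15.999, H = 1.008, S = 32.06)

.seqTo3letter <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (all(sequence %in% names(.AA3))) return(unname(.AA3[sequence]))
  if (all(sequence %in% .AA3)) return(sequence)
  bad <- setdiff(sequence, c(names(.AA3), .AA3))
  stop("unknown residue code(s): ", paste(bad, collapse = ", "))
}

.makeAtomTable <- function(resnames) {
  rows <- lapply(seq_along(resnames), function(i) {
    nm <- c("N", "CA", "C", "O")
    if (resnames[i] == "PRO") nm <- c(nm, "CD")
    el <- substr(nm, 1, 1)
    data.frame(name = nm, resid = i, resname = resnames[i], element = el,
               mass = unname(.ELEMENT_MASS[el]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# precomputed per-residue atom indices for fast chain building
.chainLayout <- function(resnames) {
  atoms <- .makeAtomTable(resnames)
  n <- length(resnames)
  iN <- iCA <- iC <- iO <- iCD <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sel <- which(atoms$resid == i)
    nm <- atoms$name[sel]
    iN[i] <- sel[nm == "N"]; iCA[i] <- sel[nm == "CA"]
    iC[i] <- sel[nm == "C"]; iO[i] <- sel[nm == "O"]
    if ("CD" %in% nm) iCD[i] <- sel[nm == "CD"]
  }
  list(atoms = atoms, iN = iN, iCA = iCA, iC = iC, iO = iO, iCD = iCD)
}

# internal-coordinate chain extension on a precomputed layout; returns the
# raw coordinate matrix (nm)
.buildBackboneXYZ <- function(layout, phi, psi, omega, geometry) {
  L <- geometry$lengths
  A <- geometry$angles
  n <- length(layout$iN)
  xyz <- matrix(NA_real_, nrow(layout$atoms), 3)
  pN <- c(0, 0, 0)
  pCA <- c(L[["nca"]], 0, 0)
  pC <- .placeAtom(c(0, 1, 0), pN, pCA, L[["cac"]], A[["ncac"]], phi[1])
  xyz[layout$iN[1], ] <- pN
  xyz[layout$iCA[1], ] <- pCA
  xyz[layout$iC[1], ] <- pC
  for (i in seq_len(n)) {
    pN <- xyz[layout$iN[i], ]
    pCA <- xyz[layout$iCA[i], ]
    pC <- xyz[layout$iC[i], ]
    xyz[layout$iO[i], ] <- .placeAtom(pN, pCA, pC, L[["co"]], A[["caco"]],
                                      psi[i] + 180)
    if (i < n) {
      pN2 <- .placeAtom(pN, pCA, pC, L[["cn"]], A[["cacn"]], psi[i])
      pCA2 <- .placeAtom(pCA, pC, pN2, L[["nca"]], A[["cnca"]], omega[i + 1])
      pC2 <- .placeAtom(pC, pN2, pCA2, L[["cac"]], A[["ncac"]], phi[i + 1])
      xyz[layout$iN[i + 1], ] <- pN2
      xyz[layout$iCA[i + 1], ] <- pCA2
      xyz[layout$iC[i + 1], ] <- pC2
      if (!is.na(layout$iCD[i + 1]))
        xyz[layout$iCD[i + 1], ] <- .placeAtom(pCA, pC, pN2, L[["ncd"]],
                                               A[["cncd"]], omega[i + 1] + 180)
    }
  }
  xyz
}

#' Build a peptide backbone from internal coordinates
#'
#' Constructs Cartesian coordinates for a peptide backbone (N, CA, C, O per
#' residue; prolines also get CD) by NeRF-style internal-coordinate chain
#' extension given per-residue phi, psi and omega dihedrals.
#'
#' Conventions: \code{omega[i]} is the torsion about the peptide bond
#' preceding residue i (CA[i-1], C[i-1], N[i], CA[i]); \code{omega[1]} is
#' unused.  \code{psi[n]} only orients the C-terminal carbonyl oxygen.
#' \code{phi[1]} orients the first carbonyl relative to an arbitrary
#' reference frame (there is no preceding carbonyl carbon).  The carbonyl
#' oxygen is placed anti to the following amide nitrogen; the proline CD is
#' placed in the amide plane opposite the preceding CA.
#'
#' @param sequence peptide sequence, one-letter string or vector of 1- or
#'   3-letter codes; length >= 2.
#' @param phi,psi,omega numeric vectors of dihedrals in degrees, one per
#'   residue.
#' @param geometry bond lengths/angles from \code{\link{backboneGeometry}}.
#' @return A \linkS4class{Conformer}.
#' @examples
#' conf <- buildBackbone("AAPA", phi = c(-60, -75, -65, -120),
#'                       psi = c(145, 150, 150, 130),
#'                       omega = c(180, 180, 0, 180))
#' classifyIsomer(backboneDihedrals(conf)$omega[3])
#' @export
buildBackbone <- function(sequence, phi, psi, omega,
                          geometry = backboneGeometry()) {
  resnames <- .seqTo3letter(sequence)
  n <- length(resnames)
  if (n < 2L) stop("sequence must have at least 2 residues")
  for (nmv in c("phi", "psi", "omega")) {
    v <- get(nmv)
    if (length(v) != n || any(!is.finite(v)))
      stop(sprintf("%s must supply one finite dihedral for every residue (missing for residue %d)",
                   nmv, if (length(v) < n) length(v) + 1L else which(!is.finite(v))[1]))
  }
  layout <- .chainLayout(resnames)
  xyz <- .buildBackboneXYZ(layout, phi, psi, omega, geometry)
  new("Conformer", atoms = layout$atoms, coords = xyz)
}

#' Backbone dihedrals of a conformer
#'
#' Measures phi (C[i-1], N, CA, C), psi (N, CA, C, N[i+1]) and omega
#' (CA[i-1], C[i-1], N, CA) for every residue; angles that require a
#' neighbouring residue are NA at the termini.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @return data.frame with columns \code{resid}, \code{resname}, \code{phi},
#'   \code{psi}, \code{omega} (degrees).
#' @export
backboneDihedrals <- function(conformer) {
  atoms <- conformer@atoms
  n <- length(unique(atoms$resid))
  res <- data.frame(resid = seq_len(n),
                    resname = atoms$resname[!duplicated(atoms$resid)],
                    phi = NA_real_, psi = NA_real_, omega = NA_real_)
  ai <- function(r, nm) .atomIndex(atoms, r, nm)
  for (i in seq_len(n)) {
    if (i > 1) {
      res$phi[i] <- measureDihedral(conformer, c(ai(i - 1, "C"), ai(i, "N"),
                                                 ai(i, "CA"), ai(i, "C")))
      res$omega[i] <- measureDihedral(conformer, c(ai(i - 1, "CA"), ai(i - 1, "C"),
                                                   ai(i, "N"), ai(i, "CA")))
    }
    if (i < n)
      res$psi[i] <- measureDihedral(conformer, c(ai(i, "N"), ai(i, "CA"),
                                                 ai(i, "C"), ai(i + 1, "N")))
  }
  res
}

#' Zeta improper dihedral at a proline
#'
#' The improper torsion (CA[i-1], O[i-1], CD[i], CA[i]) used as a collective
#' variable to enhance and monitor proline cis/trans isomerization together
#' with psi.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param resid 1-based index of a proline residue (>= 2).
#' @return Angle in degrees.
#' @export
zetaAngle <- function(conformer, resid) {
  atoms <- conformer@atoms
  if (atoms$resname[match(resid, atoms$resid)] != "PRO")
    stop(sprintf("residue %d is not a proline; zeta is defined at prolines only", resid))
  if (resid < 2) stop("zeta requires a preceding residue")
  measureDihedral(conformer,
                  c(.atomIndex(atoms, resid - 1, "CA"),
                    .atomIndex(atoms, resid - 1, "O"),
                    .atomIndex(atoms, resid, "CD"),
                    .atomIndex(atoms, resid, "CA")))
}
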