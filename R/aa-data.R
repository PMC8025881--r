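# Amino-acid reference data: one/three letter codes, eukaryotic residue
# frequencies, side-chain internal-coordinate (Z-matrix) tables, canonical
# rotamer chi angles, and atom weights used for density rendering.

#' Canonical amino-acid order
#'
#' The 20 standard one-letter codes in alphabetical order. This fixed order
#' is the tie-breaking order used everywhere a deterministic choice among
#' residue types is needed (argmax ties in scoring, pseudo-sequence calls).
#'
#' @format Character vector of length 20.
#' @export
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ORDER
#' @format `AA_THREE` is the matching vector of three-letter codes.
#' @export
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' @rdname AA_ORDER
#' @format `AA_ONE` maps three-letter codes back to one-letter codes.
#' @export
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Eukaryotic amino-acid frequencies
#'
#' Background residue frequencies of eukaryotic proteins (King & Jukes,
#' 1969), normalized to sum to one, in [AA_ORDER] order. These are the
#' default composition for the random sequences of the null adjustment and
#' for decoy databases.
#'
#' @format Named numeric vector of length 20 summing to 1.
#' @export
kj_frequencies <- local({
  f <- c(A = 7.4, C = 3.3, D = 5.9, E = 5.8, F = 4.0, G = 7.4, H = 2.9,
         I = 3.8, K = 7.2, L = 7.6, M = 1.8, N = 4.4, P = 5.0, Q = 3.7,
         R = 4.2, S = 8.1, T = 6.2, V = 6.8, W = 1.3, Y = 3.3)
  f / sum(f)
})

# Approximate electron counts used as Gaussian-atom weights when rendering
# density; keyed by element symbol (first character of the atom name).
.element_weight <- c(C = 6, N = 7, O = 8, S = 16)

# Standard main-chain geometry (Engh-Huber-like). The residue standard frame
# has CA at the origin, C on the +x axis and N in the xy-plane with positive
# y (see build_frame()).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

# Standard-frame backbone atom positions implied by .bb_geom.
.std_backbone <- local({
  a <- .bb_geom$ang_n_ca_c * pi / 180
  list(
    N  = c(.bb_geom$n_ca * cos(a), .bb_geom$n_ca * sin(a), 0),
    CA = c(0, 0, 0),
    C  = c(.bb_geom$ca_c, 0, 0)
  )
})

# Side-chain Z-matrix rows: atom placed at `bond` Angstrom from p1, with
# angle atom-p1-p2 and torsion atom-p1-p2-p3. The torsion is `off` degrees
# if ref == "none", otherwise chi[ref] + off. CB rows are shared: torsion
# CB-CA-N-C = +122.5 degrees gives L-chirality.
.zrow <- function(atom, p1, p2, p3, bond, angle, ref, off) {
  list(atom = atom, p1 = p1, p2 = p2, p3 = p3,
       bond = bond, angle = angle, ref = ref, off = off)
}

.cb_row <- function(angle = 110.5) .zrow("CB", "CA", "N", "C", 1.530, angle, "none", 122.5)

.sidechain_zmat <- list(
  ALA = list(.cb_row()),
  GLY = list(),
  SER = list(.cb_row(),
             .zrow("OG",  "CB", "CA", "N", 1.417, 110.8, "chi1", 0)),
  CYS = list(.cb_row(),
             .zrow("SG",  "CB", "CA", "N", 1.808, 113.8, "chi1", 0)),
  THR = list(.cb_row(),
             .zrow("OG1", "CB", "CA", "N", 1.433, 109.6, "chi1", 0),
             .zrow("CG2", "CB", "CA", "N", 1.521, 110.5, "chi1", -122.5)),
  VAL = list(.cb_row(),
             .zrow("CG1", "CB", "CA", "N", 1.527, 110.5, "chi1", 0),
             .zrow("CG2", "CB", "CA", "N", 1.527, 110.5, "chi1", 122.5)),
  ILE = list(.cb_row(),
             .zrow("CG1", "CB", "CA", "N", 1.530, 110.4, "chi1", 0),
             .zrow("CG2", "CB", "CA", "N", 1.521, 110.5, "chi1", -122.5),
             .zrow("CD1", "CG1", "CB", "CA", 1.513, 113.8, "chi2", 0)),
  LEU = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.530, 116.3, "chi1", 0),
             .zrow("CD1", "CG", "CB", "CA", 1.521, 110.7, "chi2", 0),
             .zrow("CD2", "CG", "CB", "CA", 1.521, 110.7, "chi2", 122.5)),
  ASP = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.516, 112.6, "chi1", 0),
             .zrow("OD1", "CG", "CB", "CA", 1.249, 118.4, "chi2", 0),
             .zrow("OD2", "CG", "CB", "CA", 1.249, 118.4, "chi2", 180)),
  ASN = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.516, 112.6, "chi1", 0),
             .zrow("OD1", "CG", "CB", "CA", 1.231, 120.8, "chi2", 0),
             .zrow("ND2", "CG", "CB", "CA", 1.328, 116.4, "chi2", 180)),
  GLU = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.520, 114.1, "chi1", 0),
             .zrow("CD",  "CG", "CB", "CA", 1.516, 112.6, "chi2", 0),
             .zrow("OE1", "CD", "CG", "CB", 1.249, 118.4, "none", 0),
             .zrow("OE2", "CD", "CG", "CB", 1.249, 118.4, "none", 180)),
  GLN = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.520, 114.1, "chi1", 0),
             .zrow("CD",  "CG", "CB", "CA", 1.516, 112.6, "chi2", 0),
             .zrow("OE1", "CD", "CG", "CB", 1.231, 120.8, "none", 0),
             .zrow("NE2", "CD", "CG", "CB", 1.328, 116.4, "none", 180)),
  MET = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.520, 114.1, "chi1", 0),
             .zrow("SD",  "CG", "CB", "CA", 1.803, 112.7, "chi2", 0),
             .zrow("CE",  "SD", "CG", "CB", 1.791, 100.9, "none", 180)),
  LYS = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.520, 114.1, "chi1", 0),
             .zrow("CD",  "CG", "CB", "CA", 1.520, 111.3, "chi2", 0),
             .zrow("CE",  "CD", "CG", "CB", 1.520, 111.3, "none", 180),
             .zrow("NZ",  "CE", "CD", "CG", 1.489, 111.9, "none", 180)),
  ARG = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.520, 114.1, "chi1", 0),
             .zrow("CD",  "CG", "CB", "CA", 1.520, 111.3, "chi2", 0),
             .zrow("NE",  "CD", "CG", "CB", 1.460, 112.0, "none", 180),
             .zrow("CZ",  "NE", "CD", "CG", 1.329, 124.2, "none", 180),
             .zrow("NH1", "CZ", "NE", "CD", 1.326, 120.0, "none", 0),
             .zrow("NH2", "CZ", "NE", "CD", 1.326, 120.0, "none", 180)),
  PHE = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.502, 113.8, "chi1", 0),
             .zrow("CD1", "CG", "CB", "CA", 1.384, 120.7, "chi2", 0),
             .zrow("CD2", "CG", "CB", "CA", 1.384, 120.7, "chi2", 180),
             .zrow("CE1", "CD1", "CG", "CD2", 1.382, 120.0, "none", 0),
             .zrow("CE2", "CD2", "CG", "CD1", 1.382, 120.0, "none", 0),
             .zrow("CZ",  "CE1", "CD1", "CG", 1.382, 120.0, "none", 0)),
  TYR = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.512, 113.8, "chi1", 0),
             .zrow("CD1", "CG", "CB", "CA", 1.389, 120.8, "chi2", 0),
             .zrow("CD2", "CG", "CB", "CA", 1.389, 120.8, "chi2", 180),
             .zrow("CE1", "CD1", "CG", "CD2", 1.382, 120.0, "none", 0),
             .zrow("CE2", "CD2", "CG", "CD1", 1.382, 120.0, "none", 0),
             .zrow("CZ",  "CE1", "CD1", "CG", 1.378, 120.0, "none", 0),
             .zrow("OH",  "CZ", "CE1", "CD1", 1.376, 119.9, "none", 180)),
  HIS = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.497, 113.7, "chi1", 0),
             .zrow("ND1", "CG", "CB", "CA", 1.371, 122.7, "chi2", 0),
             .zrow("CD2", "CG", "CB", "CA", 1.356, 131.6, "chi2", 180),
             .zrow("CE1", "ND1", "CG", "CD2", 1.319, 109.0, "none", 0),
             .zrow("NE2", "CD2", "CG", "ND1", 1.374, 107.0, "none", 0)),
  TRP = list(.cb_row(),
             .zrow("CG",  "CB", "CA", "N", 1.498, 113.6, "chi1", 0),
             .zrow("CD1", "CG", "CB", "CA", 1.365, 126.9, "chi2", 0),
             .zrow("CD2", "CG", "CB", "CA", 1.433, 126.6, "chi2", 180),
             .zrow("NE1", "CD1", "CG", "CD2", 1.374, 110.2, "none", 0),
             .zrow("CE2", "CD2", "CG", "CD1", 1.409, 106.7, "none", 0),
             .zrow("CE3", "CD2", "CG", "CD1", 1.398, 130.9, "none", 180),
             .zrow("CZ2", "CE2", "CD2", "CG", 1.394, 122.4, "none", 180),
             .zrow("CZ3", "CE3", "CD2", "CE2", 1.382, 118.8, "none", 0),
             .zrow("CH2", "CZ2", "CE2", "CD2", 1.368, 117.5, "none", 0)),
  PRO = list(.zrow("CB", "CA", "N", "C", 1.530, 103.2, "none", 115.0),
             .zrow("CG", "CB", "CA", "N", 1.492, 104.5, "chi1", 0),
             .zrow("CD", "CG", "CB", "CA", 1.503, 106.1, "chi2", 0))
)

# Canonical rotamer chi-angle table (degrees). Each row of a residue's
# matrix is one rotamer; columns are chi1, chi2 as far as rotameric.
# Distal torsions past chi2 are fixed extended/planar in the Z-matrix.
.rotamer_chis <- local({
  g3 <- c(-60, 180, 60)
  grid2 <- as.matrix(expand.grid(chi1 = g3, chi2 = g3))
  chi1_only <- matrix(g3, ncol = 1, dimnames = list(NULL, "chi1"))
  none <- matrix(numeric(0), nrow = 1, ncol = 0)
  aromatic2 <- function(chi2s) as.matrix(expand.grid(chi1 = g3, chi2 = chi2s))
  list(
    ALA = none, GLY = none,
    SER = chi1_only, CYS = chi1_only, THR = chi1_only, VAL = chi1_only,
    ILE = grid2, LEU = grid2, ASP = grid2, ASN = grid2,
    GLU = grid2, GLN = grid2, MET = grid2, LYS = grid2, ARG = grid2,
    PHE = aromatic2(90), TYR = aromatic2(90),
    HIS = aromatic2(c(-90, 90)), TRP = aromatic2(c(-90, 90)),
    PRO = matrix(c(29, -37, -25, 39), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("chi1", "chi2")))
  )
})

# chi-defining atom quadruplets, derived from the Z-matrix: chi1 is
# N-CA-CB-G where G is the atom whose torsion reference is chi1 with zero
# offset, chi2 is CA-CB-G-D likewise.
.chi_atoms <- local({
  out <- list()
  for (res in names(.sidechain_zmat)) {
    zm <- .sidechain_zmat[[res]]
    defs <- list()
    for (chi in c("chi1", "chi2")) {
      hit <- Filter(function(r) r$ref == chi && r$off == 0, zm)
      if (length(hit)) {
        r <- hit[[1]]
        defs[[chi]] <- c(r$p3, r$p2, r$p1, r$atom)
      }
    }
    out[[res]] <- defs
  }
  out
})

#' Number of canonical rotamers per residue type
#'
#' @return Named integer vector over the three-letter residue codes.
#' @export
rotamer_counts <- function() {
  vapply(.rotamer_chis, nrow, integer(1))
}
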