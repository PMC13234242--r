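# Versioned physical-constant and geometry tables used across the package.

#' Monoisotopic residue masses
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues, i.e. the
#' mass each residue contributes inside a peptide chain (free amino-acid mass
#' minus water). A peptide's neutral mass is the sum of its residue masses
#' plus one water.
#'
#' @format Named numeric vector, one-letter residue codes as names.
#' @export
aa_residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic masses of water and the proton
#'
#' @name mass_constants
#' @export
mass_water <- 18.0105646

#' @rdname mass_constants
#' @export
mass_proton <- 1.007276

# one-letter <-> three-letter residue codes (SNN handled separately as the
# cyclized form of N)
.aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' Convert between one- and three-letter residue codes
#'
#' @param x character vector of residue codes.
#' @return character vector of the converted codes; unknown codes map to `NA`
#'   except `"SNN"`, which maps to `"N"` (a cyclized asparagine).
#' @export
aa321 <- function(x) {
  out <- .aa1[match(toupper(x), .aa3)]
  out[toupper(x) == "SNN"] <- "N"
  out
}

#' @rdname aa321
#' @export
aa123 <- function(x) .aa3[match(toupper(x), .aa1)]

# Three-letter codes treated as polymer residues (protein) by default
# selections; SNN is a first-class member.
.protein_resids <- c(.aa3, "SNN")

.water_resids <- c("HOH", "WAT", "DOD", "H2O", "SOL")

# Ideal covalent geometry used by the peptide builder (lengths in Angstrom,
# angles in degrees).  The fidelity target of the builder is exact torsion
# round-trip, not force-field realism.
.ideal_geom <- list(
  b_N_CA  = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_CA_CB = 1.530, b_CB_CG = 1.516, b_CG_OD1 = 1.231, b_CG_ND2 = 1.328,
  b_CG_OD2 = 1.249,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8,
  a_N_CA_CB = 110.5, a_CA_CB_CG = 112.6, a_CB_CG_OD1 = 120.8,
  a_CB_CG_ND2 = 116.4,
  # torsion of CB about the N-CA axis in the dihedral(C, N, CA, CB) frame;
  # -122.6 deg places CB with L-configuration (the value measured across
  # L residues of deposited structures is about -123)
  t_CB = -122.6
)

# chi1 is N-CA-CB-X and chi2 is CA-CB-CG-X; the tables give X per residue.
# For SNN the ring atoms map CB->CB, CG->CG, OD1->OD1 so the same torsion
# definitions apply to the cyclic form.
.chi1_atom <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1",
  SNN = "CG"
)
.chi2_atom <- c(
  ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD", HIS = "ND1",
  ILE = "CD1", LEU = "CD1", LYS = "CD", MET = "SD", PHE = "CD1", PRO = "CD",
  TRP = "CD1", TYR = "CD1", SNN = "OD1"
)
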