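# Amino-acid topology: idealized side-chain internal coordinates, chi
# dihedral definitions, polar hydrogen construction, and the table of polar
# atoms / antecedent points that define hydrogen-bond half-sites. Atom names
# follow CHARMM PDB conventions for polar hydrogens (HN, HG1, HH11, ...).

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Backbone atom labels (both CHARMM and wwPDB terminal/amide spellings).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "H", "HN", "HN1", "HN2", "HN3",
                    "H1", "H2", "H3", "OXT", "OT1", "OT2", "HA", "HA1",
                    "HA2", "HA3")

# Polar amino acids a mutable paratope residue may be designed into (the
# side-chain half-site alphabet).
POLAR_ALPHABET <- c("SER", "THR", "TYR", "ASN", "ASP", "GLU", "GLN", "HIS",
                    "TRP", "ARG", "LYS")

# Clash-rescue cascade alphabets (ordered as searched).
CASCADE_POLAR <- c("SER", "THR", "ASN", "ASP", "HIS")
CASCADE_NONPOLAR <- c("ALA", "VAL", "LEU", "ILE", "PHE")

# Minimum number of realized H-bonds required for a polar clash mutation.
CASCADE_POLAR_MIN_HBONDS <- c(SER = 1, THR = 1, ASN = 2, ASP = 2, HIS = 2)

element_of <- function(name) {
  n <- gsub("[0-9']", "", name)
  ifelse(substr(n, 1, 1) == "H", "H", substr(n, 1, 1))
}

# Heavy-atom van der Waals radii (Angstrom) for surface-area calculations.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# One z-matrix row: atom `name` bonded to `c` (bond Angstrom), angle
# name-c-b (degrees), dihedral a-b-c-name. `chi` > 0 means the dihedral is
# chi_k + `off`; chi == 0 means the fixed value `tors`.
za <- function(name, a, b, c, bond, angle, tors = 0, chi = 0, off = 0) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             tors = tors, chi = chi, off = off, stringsAsFactors = FALSE)
}

# CB is built identically for all residue types (L-chirality).
.zcb <- za("CB", "C", "N", "CA", 1.53, 110.4, 122.5)

SIDECHAIN_ZMAT <- list(
  GLY = data.frame(name = character(0), a = character(0), b = character(0),
                   c = character(0), bond = numeric(0), angle = numeric(0),
                   tors = numeric(0), chi = numeric(0), off = numeric(0),
                   stringsAsFactors = FALSE),
  ALA = .zcb,
  SER = rbind(.zcb,
    za("OG",  "N",  "CA", "CB", 1.417, 110.8, chi = 1),
    za("HG1", "CA", "CB", "OG", 0.96, 109.5, 180)),
  CYS = rbind(.zcb,
    za("SG", "N", "CA", "CB", 1.81, 114.4, chi = 1)),
  THR = rbind(.zcb,
    za("OG1", "N",  "CA", "CB",  1.433, 109.6, chi = 1),
    za("CG2", "N",  "CA", "CB",  1.52, 110.5, chi = 1, off = 121.5),
    za("HG1", "CA", "CB", "OG1", 0.96, 109.5, 180)),
  VAL = rbind(.zcb,
    za("CG1", "N", "CA", "CB", 1.52, 110.5, chi = 1),
    za("CG2", "N", "CA", "CB", 1.52, 110.5, chi = 1, off = -121.6)),
  ILE = rbind(.zcb,
    za("CG1", "N",  "CA", "CB",  1.53, 110.4, chi = 1),
    za("CG2", "N",  "CA", "CB",  1.52, 110.5, chi = 1, off = 128.7),
    za("CD1", "CA", "CB", "CG1", 1.51, 113.8, chi = 2)),
  LEU = rbind(.zcb,
    za("CG",  "N",  "CA", "CB", 1.53, 116.3, chi = 1),
    za("CD1", "CA", "CB", "CG", 1.52, 110.7, chi = 2),
    za("CD2", "CA", "CB", "CG", 1.52, 110.7, chi = 2, off = -120)),
  PRO = rbind(.zcb,
    za("CG", "N",  "CA", "CB", 1.50, 104.5, chi = 1),
    za("CD", "CA", "CB", "CG", 1.51, 106.0, chi = 2)),
  MET = rbind(.zcb,
    za("CG", "N",  "CA", "CB", 1.52, 114.1, chi = 1),
    za("SD", "CA", "CB", "CG", 1.80, 112.7, chi = 2),
    za("CE", "CB", "CG", "SD", 1.79, 100.9, chi = 3)),
  PHE = rbind(.zcb,
    za("CG",  "N",  "CA",  "CB",  1.50, 113.8, chi = 1),
    za("CD1", "CA", "CB",  "CG",  1.39, 120.7, chi = 2),
    za("CD2", "CA", "CB",  "CG",  1.39, 120.7, chi = 2, off = 180),
    za("CE1", "CB", "CG",  "CD1", 1.39, 121.0, 180),
    za("CE2", "CB", "CG",  "CD2", 1.39, 121.0, 180),
    za("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = rbind(.zcb,
    za("CG",  "N",   "CA",  "CB",  1.50, 113.8, chi = 1),
    za("CD1", "CA",  "CB",  "CG",  1.39, 120.7, chi = 2),
    za("CD2", "CA",  "CB",  "CG",  1.39, 120.7, chi = 2, off = 180),
    za("CE1", "CB",  "CG",  "CD1", 1.39, 121.0, 180),
    za("CE2", "CB",  "CG",  "CD2", 1.39, 121.0, 180),
    za("CZ",  "CG",  "CD1", "CE1", 1.39, 120.0, 0),
    za("OH",  "CD1", "CE1", "CZ",  1.38, 120.0, 180),
    za("HH",  "CE1", "CZ",  "OH",  0.96, 109.5, 180)),
  TRP = rbind(.zcb,
    za("CG",  "N",   "CA",  "CB",  1.50, 113.6, chi = 1),
    za("CD1", "CA",  "CB",  "CG",  1.37, 127.0, chi = 2),
    za("CD2", "CA",  "CB",  "CG",  1.43, 126.5, chi = 2, off = 180),
    za("NE1", "CB",  "CG",  "CD1", 1.38, 110.0, 180),
    za("CE2", "CB",  "CG",  "CD2", 1.41, 107.5, 180),
    za("CE3", "CB",  "CG",  "CD2", 1.40, 132.1, 0),
    za("CZ2", "CG",  "CD2", "CE2", 1.40, 122.4, 180),
    za("CZ3", "CG",  "CD2", "CE3", 1.39, 117.8, 180),
    za("CH2", "CD2", "CE2", "CZ2", 1.37, 116.8, 0),
    za("HE1", "CG",  "CD1", "NE1", 1.01, 125.5, 180)),
  ASP = rbind(.zcb,
    za("CG",  "N",  "CA", "CB", 1.52, 112.6, chi = 1),
    za("OD1", "CA", "CB", "CG", 1.25, 118.4, chi = 2),
    za("OD2", "CA", "CB", "CG", 1.25, 118.4, chi = 2, off = 180)),
  ASN = rbind(.zcb,
    za("CG",   "N",   "CA", "CB",  1.52, 112.6, chi = 1),
    za("OD1",  "CA",  "CB", "CG",  1.23, 120.8, chi = 2),
    za("ND2",  "CA",  "CB", "CG",  1.33, 116.4, chi = 2, off = 180),
    za("HD21", "OD1", "CG", "ND2", 1.00, 119.5, 180),
    za("HD22", "OD1", "CG", "ND2", 1.00, 119.5, 0)),
  GLU = rbind(.zcb,
    za("CG",  "N",  "CA", "CB", 1.52, 114.1, chi = 1),
    za("CD",  "CA", "CB", "CG", 1.52, 112.6, chi = 2),
    za("OE1", "CB", "CG", "CD", 1.25, 118.4, chi = 3),
    za("OE2", "CB", "CG", "CD", 1.25, 118.4, chi = 3, off = 180)),
  GLN = rbind(.zcb,
    za("CG",   "N",   "CA", "CB",  1.52, 114.1, chi = 1),
    za("CD",   "CA",  "CB", "CG",  1.52, 112.6, chi = 2),
    za("OE1",  "CB",  "CG", "CD",  1.23, 120.8, chi = 3),
    za("NE2",  "CB",  "CG", "CD",  1.33, 116.4, chi = 3, off = 180),
    za("HE21", "OE1", "CD", "NE2", 1.00, 119.5, 180),
    za("HE22", "OE1", "CD", "NE2", 1.00, 119.5, 0)),
  HIS = rbind(.zcb,
    za("CG",  "N",  "CA",  "CB",  1.50, 113.8, chi = 1),
    za("ND1", "CA", "CB",  "CG",  1.38, 122.0, chi = 2),
    za("CD2", "CA", "CB",  "CG",  1.36, 132.0, chi = 2, off = 180),
    za("CE1", "CB", "CG",  "ND1", 1.32, 109.0, 180),
    za("NE2", "CG", "ND1", "CE1", 1.32, 111.7, 0),
    za("HD1", "CB", "CG",  "ND1", 1.00, 125.6, 0)),
  LYS = rbind(.zcb,
    za("CG",  "N",  "CA", "CB", 1.52, 114.1, chi = 1),
    za("CD",  "CA", "CB", "CG", 1.52, 111.3, chi = 2),
    za("CE",  "CB", "CG", "CD", 1.52, 111.3, chi = 3),
    za("NZ",  "CG", "CD", "CE", 1.49, 112.0, chi = 4),
    za("HZ1", "CD", "CE", "NZ", 1.04, 109.5, 180),
    za("HZ2", "CD", "CE", "NZ", 1.04, 109.5, 60),
    za("HZ3", "CD", "CE", "NZ", 1.04, 109.5, -60)),
  ARG = rbind(.zcb,
    za("CG",   "N",   "CA", "CB",  1.52, 114.1, chi = 1),
    za("CD",   "CA",  "CB", "CG",  1.52, 111.3, chi = 2),
    za("NE",   "CB",  "CG", "CD",  1.46, 112.0, chi = 3),
    za("CZ",   "CG",  "CD", "NE",  1.33, 124.2, chi = 4),
    za("NH1",  "CD",  "NE", "CZ",  1.33, 120.0, 0),
    za("NH2",  "CD",  "NE", "CZ",  1.33, 120.0, 180),
    za("HE",   "NH1", "CZ", "NE",  1.00, 119.0, 180),
    za("HH11", "NE",  "CZ", "NH1", 1.00, 120.0, 0),
    za("HH12", "NE",  "CZ", "NH1", 1.00, 120.0, 180),
    za("HH21", "NE",  "CZ", "NH2", 1.00, 120.0, 0),
    za("HH22", "NE",  "CZ", "NH2", 1.00, 120.0, 180))
)

# Chi dihedral atom quadruples per residue type.
CHI_ATOMS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ALA = list(),
  GLY = list()
)

n_chi <- function(aa) length(CHI_ATOMS[[aa]])

# Polar atoms and their antecedent points defining hydrogen-bond half-sites.
# `ant2` non-NA marks a midpoint antecedent. Backbone rows (aa == "BB") apply
# to every residue type; the terminal rows (OT1/OT2, HN1-HN3) only fire when
# those atoms exist in the structure.
HALF_SITE_TABLE <- local({
  r <- function(aa, atom, ant1, ant2 = NA_character_)
    data.frame(aa = aa, atom = atom, ant1 = ant1, ant2 = ant2,
               stringsAsFactors = FALSE)
  rbind(
    r("BB", "O", "C"), r("BB", "OT1", "C"), r("BB", "OT2", "C"),
    r("BB", "HN", "N"), r("BB", "HN1", "N"), r("BB", "HN2", "N"),
    r("BB", "HN3", "N"),
    r("ARG", "HE", "NE"),
    r("ARG", "HH11", "NH1"), r("ARG", "HH12", "NH1"),
    r("ARG", "HH21", "NH2"), r("ARG", "HH22", "NH2"),
    r("LYS", "HZ1", "NZ"), r("LYS", "HZ2", "NZ"), r("LYS", "HZ3", "NZ"),
    r("ASP", "OD1", "CG"), r("ASP", "OD2", "CG"),
    r("GLU", "OE1", "CD"), r("GLU", "OE2", "CD"),
    r("SER", "HG1", "OG"), r("SER", "OG", "HG1", "CB"),
    r("THR", "HG1", "OG1"), r("THR", "OG1", "HG1", "CB"),
    r("TYR", "HH", "OH"), r("TYR", "OH", "HH", "CZ"),
    r("ASN", "OD1", "CG"), r("ASN", "HD21", "ND2"), r("ASN", "HD22", "ND2"),
    r("GLN", "OE1", "CD"), r("GLN", "HE21", "NE2"), r("GLN", "HE22", "NE2"),
    r("HIS", "HD1", "ND1"), r("HIS", "NE2", "CD2", "CE1"),
    r("TRP", "HE1", "NE1")
  )
})
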