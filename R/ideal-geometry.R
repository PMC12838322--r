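# Ideal covalent geometry used by the synthetic builder. One self-consistent
# Engh-Huber-style set; every downstream check is a round-trip or relative
# comparison, so internal consistency is what matters.

.BB <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  a_N_CA_C = 111.2, a_CA_C_N = 116.6, a_C_N_CA = 121.7, a_CA_C_O = 120.1,
  # improper torsion N-C-CA-CB fixing L-chirality of the CB branch
  b_CA_CB = 1.530, a_C_CA_CB = 110.1, t_N_C_CA_CB = 122.6
)

.zrow <- function(name, a, b, c, r, theta, chi) {
  data.frame(name = name, a = a, b = b, c = c, r = r, theta = theta,
             chi = chi, stringsAsFactors = FALSE)
}

# Z-matrix side-chain templates in a canonical (mostly all-trans) rotamer.
# Each row places one atom: bond to 'c', angle (b,c,new), torsion (a,b,c,new).
.SIDECHAIN_ZMAT <- list(
  ALA = NULL,
  SER = .zrow("OG", "N", "CA", "CB", 1.417, 110.8, 180),
  CYS = .zrow("SG", "N", "CA", "CB", 1.808, 113.8, 180),
  THR = rbind(.zrow("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
              .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
  VAL = rbind(.zrow("CG1", "N", "CA", "CB", 1.527, 110.5, 180),
              .zrow("CG2", "N", "CA", "CB", 1.527, 110.5, -60)),
  LEU = rbind(.zrow("CG", "N", "CA", "CB", 1.530, 116.3, 180),
              .zrow("CD1", "CA", "CB", "CG", 1.524, 110.7, 180),
              .zrow("CD2", "CA", "CB", "CG", 1.524, 110.7, -60)),
  ILE = rbind(.zrow("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
              .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
              .zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = rbind(.zrow("CG", "N", "CA", "CB", 1.530, 114.1, 180),
              .zrow("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
              .zrow("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
  PRO = rbind(.zrow("CG", "N", "CA", "CB", 1.492, 104.5, 30),
              .zrow("CD", "CA", "CB", "CG", 1.503, 106.1, -35)),
  ASP = rbind(.zrow("CG", "N", "CA", "CB", 1.516, 112.6, 180),
              .zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
              .zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = rbind(.zrow("CG", "N", "CA", "CB", 1.516, 112.6, 180),
              .zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
              .zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = rbind(.zrow("CG", "N", "CA", "CB", 1.530, 114.1, 180),
              .zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
              .zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
              .zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = rbind(.zrow("CG", "N", "CA", "CB", 1.530, 114.1, 180),
              .zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
              .zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
              .zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = rbind(.zrow("CG", "N", "CA", "CB", 1.530, 114.1, 180),
              .zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
              .zrow("CE", "CB", "CG", "CD", 1.520, 111.3, 180),
              .zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = rbind(.zrow("CG", "N", "CA", "CB", 1.530, 114.1, 180),
              .zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
              .zrow("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
              .zrow("CZ", "CG", "CD", "NE", 1.330, 124.2, 180),
              .zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
              .zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  PHE = rbind(.zrow("CG", "N", "CA", "CB", 1.502, 113.8, 180),
              .zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
              .zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, -90),
              .zrow("CE1", "CB", "CG", "CD1", 1.382, 121.0, 180),
              .zrow("CE2", "CB", "CG", "CD2", 1.382, 121.0, 180),
              .zrow("CZ", "CG", "CD1", "CE1", 1.382, 119.9, 0)),
  TYR = rbind(.zrow("CG", "N", "CA", "CB", 1.502, 113.8, 180),
              .zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
              .zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, -90),
              .zrow("CE1", "CB", "CG", "CD1", 1.382, 121.0, 180),
              .zrow("CE2", "CB", "CG", "CD2", 1.382, 121.0, 180),
              .zrow("CZ", "CG", "CD1", "CE1", 1.382, 119.9, 0),
              .zrow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = rbind(.zrow("CG", "N", "CA", "CB", 1.498, 113.6, 180),
              .zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
              .zrow("CD2", "CA", "CB", "CG", 1.433, 126.6, -90),
              .zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
              .zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
              .zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
              .zrow("CZ2", "CG", "CD2", "CE2", 1.398, 122.4, 180),
              .zrow("CZ3", "CG", "CD2", "CE3", 1.391, 118.6, 180),
              .zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
  HIS = rbind(.zrow("CG", "N", "CA", "CB", 1.497, 113.8, 180),
              .zrow("ND1", "CA", "CB", "CG", 1.371, 122.7, 90),
              .zrow("CD2", "CA", "CB", "CG", 1.356, 131.0, -90),
              .zrow("CE1", "CB", "CG", "ND1", 1.319, 109.3, 180),
              .zrow("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180)),
  GLY = NULL
)

.AA3 <- names(.SIDECHAIN_ZMAT)

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.elemFromName <- function(elety) {
  first <- substr(gsub("[0-9]", "", elety), 1L, 1L)
  match.arg(first, c("C", "N", "O", "S"))
}
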