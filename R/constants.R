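## Physical constants and lookup tables shared across modules.

## Average residue (monoisotopic-free) masses in Da; a peptide's mass is the
## sum of residue masses plus one water.
.RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.WATER_MASS <- 18.0153

.AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.AA_ONE_TO_THREE <- structure(names(.AA_THREE_TO_ONE), names = .AA_THREE_TO_ONE)

## Van der Waals radii (Angstrom) by element, Bondi-style values as used by
## common SASA implementations.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

## Theoretical maximum per-residue SASA (Angstrom^2), Tien et al. 2013
## (theoretical column); reference for relative exposure.
.MAX_SASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

## Hydrophobic residues used for surface-patch and sequence diagnostics.
## Cys excluded: its burial statistics are dominated by disulfides.
.HYDROPHOBIC_THREE <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP")
.HYDROPHOBIC_ONE <- c("A", "V", "L", "I", "M", "F", "W")

.STANDARD_AA1 <- names(.AA_ONE_TO_THREE)
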