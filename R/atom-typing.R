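# Embedded atom-typing tables: residue vocabularies, van der Waals radii,
# backbone/polar flags, coarse partial charges and hydrogen-bond
# donor/acceptor assignments.  All structural descriptors are computed
# from heavy atoms only; these tables are frozen and documented here.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA3_FROM_1 <- stats::setNames(names(AA1), AA1)

# Common modified residues mapped to their parent (lenient mode only).
MODIFIED_AA <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
                 SEP = "SER", TPO = "THR", PTR = "TYR", MLY = "LYS",
                 CSO = "CYS")

DNA_RES <- c("DA", "DC", "DG", "DT", "DI", "DU")
RNA_RES <- c("A", "C", "G", "U", "I")
NA_RES <- c(DNA_RES, RNA_RES)

PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT")

# Chothia/NACCESS-style heavy-atom van der Waals radii (Angstrom).
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
               SE = 1.90, H = 1.00, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98)
VDW_DEFAULT <- 1.80

element_radius <- function(elem) {
  r <- VDW_RADII[toupper(elem)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Infer the element symbol from a PDB atom name when the element column
# is absent or blank.  Two-letter elements relevant here: SE (MSE).
element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1, 1)
  el[nm == "SE"] <- "SE"
  el
}

is_polar_element <- function(elem) toupper(elem) %in% c("N", "O")

# Coarse united-atom partial charges (elementary units).  Hydrogens are
# absent from the atom model, so the charge of each polar hydrogen is
# folded into its donor heavy atom; residues are therefore only
# approximately neutral.  Used exclusively by the screened-Coulomb
# potential summaries.
BACKBONE_CHARGES <- c(N = -0.16, CA = 0.16, C = 0.51, O = -0.51,
                      OXT = -0.51)

SIDECHAIN_CHARGES <- list(
  ARG = c(NE = 0.10, NH1 = 0.45, NH2 = 0.45),
  LYS = c(NZ = 1.00),
  ASP = c(OD1 = -0.50, OD2 = -0.50),
  GLU = c(OE1 = -0.50, OE2 = -0.50),
  HIS = c(ND1 = -0.05, NE2 = 0.05),
  SER = c(OG = -0.25, CB = 0.25),
  THR = c(OG1 = -0.25, CB = 0.25),
  TYR = c(OH = -0.25, CZ = 0.25),
  ASN = c(OD1 = -0.42, ND2 = 0.42),
  GLN = c(OE1 = -0.42, NE2 = 0.42),
  CYS = c(SG = -0.10, CB = 0.10),
  TRP = c(NE1 = -0.10, CD1 = 0.10),
  MET = c(SD = -0.10, CG = 0.05, CE = 0.05)
)

# Phosphate-centred charges for nucleotides (net -1 per phosphate).
NA_CHARGES <- c(P = 1.20, OP1 = -0.85, OP2 = -0.85, O1P = -0.85,
                O2P = -0.85, "O5'" = -0.25, "O3'" = -0.25)

atom_partial_charge <- function(res_name, atom_name, is_protein) {
  q <- numeric(length(atom_name))
  if (length(q) == 0L) return(q)
  bb <- is_protein & atom_name %in% names(BACKBONE_CHARGES)
  q[bb] <- BACKBONE_CHARGES[atom_name[bb]]
  for (i in which(is_protein & !bb)) {
    tab <- SIDECHAIN_CHARGES[[res_name[i]]]
    if (!is.null(tab) && atom_name[i] %in% names(tab))
      q[i] <- tab[[atom_name[i]]]
  }
  nb <- !is_protein & atom_name %in% names(NA_CHARGES)
  q[nb] <- NA_CHARGES[atom_name[nb]]
  q
}

# Hydrogen-bond donor / acceptor typing (heavy atoms).
PROTEIN_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG"
)

PROTEIN_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD", CYS = "SG"
)

# Nucleic-acid side: every backbone/sugar oxygen and ring nitrogen
# accepts; exocyclic amino nitrogens (and the imino N1/N3) donate.
NA_ACCEPTOR_ATOMS <- c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'",
                       "O2'", "O2", "O4", "O6", "N1", "N3", "N7")
NA_DONOR_ATOMS <- c("N1", "N2", "N3", "N4", "N6")

is_protein_donor <- function(res_name, atom_name) {
  out <- atom_name %in% PROTEIN_DONORS$backbone & res_name != "PRO"
  for (i in seq_along(atom_name)) {
    tab <- PROTEIN_DONORS[[res_name[i]]]
    if (!is.null(tab) && atom_name[i] %in% tab) out[i] <- TRUE
  }
  out
}

is_protein_acceptor <- function(res_name, atom_name) {
  out <- atom_name %in% PROTEIN_ACCEPTORS$backbone
  for (i in seq_along(atom_name)) {
    tab <- PROTEIN_ACCEPTORS[[res_name[i]]]
    if (!is.null(tab) && atom_name[i] %in% tab) out[i] <- TRUE
  }
  out
}
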