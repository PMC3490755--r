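# Residue vocabularies shared across modules.

# 20 standard amino acids, PSI-BLAST PSSM column order.
PSSM_COLUMNS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Encoding alphabet: 20 amino acids plus 'X' for unknowns and window padding.
AA_ALPHABET <- c(PSSM_COLUMNS, "X")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Modified / non-standard residues mapped to the parent amino acid; anything
# absent from both tables becomes 'X'.
AA_MODIFIED_TO_ONE <- c(
  MSE = "M", CSO = "C", CSD = "C", CME = "C", OCS = "C", SEP = "S",
  TPO = "T", PTR = "Y", HYP = "P", MLY = "K", M3L = "K", KCX = "K",
  CGU = "E", PCA = "Q", FME = "M", HIC = "H", MLZ = "K", ALY = "K",
  SAC = "S", LLP = "K"
)

RNA_RESNAMES <- c("A", "C", "G", "U", "I",
                  "RA", "RC", "RG", "RU",
                  "1MA", "2MG", "5MC", "5MU", "7MG", "H2U", "M2G", "OMC",
                  "OMG", "PSU", "4SU")

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Convert a 3-letter residue name to its 1-letter amino-acid code
#'
#' Standard residues map to their usual code, common modified residues map to
#' the parent amino acid (e.g. selenomethionine MSE to M), and anything else
#' maps to `"X"`.
#'
#' @param resname Character vector of 3-letter residue names.
#' @return Character vector of 1-letter codes.
#' @export
#' @examples
#' aa_three_to_one(c("ALA", "MSE", "XYZ"))
aa_three_to_one <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- unname(AA_THREE_TO_ONE[resname])
  mod <- is.na(out)
  out[mod] <- unname(AA_MODIFIED_TO_ONE[resname[mod]])
  out[is.na(out)] <- "X"
  out
}

is_protein_resname <- function(resname) {
  resname <- toupper(trimws(resname))
  resname %in% c(names(AA_THREE_TO_ONE), names(AA_MODIFIED_TO_ONE))
}

is_rna_resname <- function(resname) {
  toupper(trimws(resname)) %in% RNA_RESNAMES
}

rna_one_letter <- function(resname) {
  resname <- toupper(trimws(resname))
  map <- c(A = "A", C = "C", G = "G", U = "U",
           RA = "A", RC = "C", RG = "G", RU = "U")
  out <- unname(map[resname])
  out[is.na(out)] <- "X"
  out
}
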