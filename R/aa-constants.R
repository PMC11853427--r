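#' Amino-acid constant table
#'
#' Per-residue physicochemical constants used in the 36-dimensional vertex
#' feature block: average molecular weight (Da), pKa of the alpha-carboxyl
#' group, pKb of the alpha-amino group, pKx of the ionizable side chain
#' (0 for residues without one), and whole-residue hydrophobicity at pH 2 and
#' pH 7 (normalized scale, glycine = 0).
#'
#' The `"X"` row covers non-standard residues: every numeric column is the
#' mean over the 20 standard residues.
#'
#' @return A data frame with one row per residue code (20 standard + `"X"`)
#'   and columns `one`, `three`, `mw`, `pka`, `pkb`, `pkx`, `hphob_ph2`,
#'   `hphob_ph7`.
#' @export
aa_constant_table <- function() {
  tab <- data.frame(
    one   = c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    three = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN", "GLY", "HIS", "ILE",
              "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"),
    mw    = c(89.10, 174.20, 132.12, 133.11, 121.16, 147.13, 146.15, 75.07, 155.16, 131.18,
              131.18, 146.19, 149.21, 165.19, 115.13, 105.09, 119.12, 204.23, 181.19, 117.15),
    pka   = c(2.34, 2.17, 2.02, 1.88, 1.96, 2.19, 2.17, 2.34, 1.82, 2.36,
              2.36, 2.18, 2.28, 1.83, 1.99, 2.21, 2.09, 2.83, 2.20, 2.32),
    pkb   = c(9.69, 9.04, 8.80, 9.60, 10.28, 9.67, 9.13, 9.60, 9.17, 9.60,
              9.60, 8.95, 9.21, 9.13, 10.60, 9.15, 9.10, 9.39, 9.11, 9.62),
    pkx   = c(0, 12.48, 0, 3.65, 8.18, 4.25, 0, 0, 6.00, 0,
              0, 10.53, 0, 0, 0, 0, 0, 0, 10.07, 0),
    hphob_ph2 = c(47, -26, -41, -18, 52, 8, -18, 0, -42, 100,
                  100, -37, 74, 92, -46, -7, 13, 84, 49, 79),
    hphob_ph7 = c(41, -14, -28, -55, 49, -31, -10, 0, 8, 99,
                  97, -23, 74, 100, -46, -5, 13, 97, 63, 76),
    stringsAsFactors = FALSE
  )
  x_row <- data.frame(
    one = "X", three = "UNK",
    mw = mean(tab$mw), pka = mean(tab$pka), pkb = mean(tab$pkb),
    pkx = mean(tab$pkx), hphob_ph2 = mean(tab$hphob_ph2),
    hphob_ph7 = mean(tab$hphob_ph7), stringsAsFactors = FALSE
  )
  rbind(tab, x_row)
}

# fixed 21-letter residue alphabet used everywhere (one-hot order, token order)
RESIDUE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Map a three-letter residue name to its one-letter code
#'
#' The 20 standard residues map to their usual codes; every other name
#' (modified residues such as MSE, unknown ligand-like groups, ...) maps to
#' `"X"`. Total function: never errors on a non-empty name.
#'
#' @param three_letter Character vector of residue names (case-insensitive).
#' @return Character vector of one-letter codes in `{A..Y, X}`.
#' @export
residue_to_one_letter <- function(three_letter) {
  stopifnot(is.character(three_letter), all(nzchar(three_letter)))
  out <- unname(THREE_TO_ONE[toupper(three_letter)])
  out[is.na(out)] <- "X"
  out
}
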