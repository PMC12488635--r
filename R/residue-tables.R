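#' Residue property tables for the statistical descriptors
#'
#' Average molecular masses (daltons) and elemental formulas of the 20
#' standard amino acids as free molecules (not residues-in-chain): the
#' molecular-weight descriptor is defined as the plain sum of free
#' amino-acid masses, with no water-loss correction for peptide bonds,
#' and the atomic-composition descriptor counts the atoms of the free
#' molecules. Masses are the standard average (isotope-abundance
#' weighted) molecular weights; formulas are the canonical C/H/N/O/S
#' compositions (e.g. alanine C3H7NO2, cysteine C3H7NO2S).
#'
#' @return A data.frame with one row per amino acid in alphabetical
#'   one-letter order and columns `code`, `mass`, `C`, `H`, `N`, `O`,
#'   `S`.
#' @examples
#' tab <- residueTables()
#' tab[tab$code == "G", ]
#' @export
residueTables <- function() {
    .RESIDUE_TABLE
}

# one-letter code, average mass of the free amino acid (Da), atom counts
# of the free molecule for C, H, N, O, S
.RESIDUE_TABLE <- data.frame(
    code = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    mass = c( 89.09, 121.16, 133.10, 147.13, 165.19,  75.07, 155.15,
             131.17, 146.19, 131.17, 149.21, 132.12, 115.13, 146.15,
             174.20, 105.09, 119.12, 117.15, 204.23, 181.19),
    C = c(3, 3, 4, 5, 9, 2, 6, 6, 6, 6, 5, 4, 5, 5, 6, 3, 4, 5, 11, 9),
    H = c(7, 7, 7, 9, 11, 5, 9, 13, 14, 13, 11, 8, 9, 10, 14, 7, 9, 11, 12, 11),
    N = c(1, 1, 1, 1, 1, 1, 3, 1, 2, 1, 1, 2, 1, 2, 4, 1, 1, 1, 2, 1),
    O = c(2, 2, 4, 4, 2, 2, 2, 2, 2, 2, 2, 3, 2, 3, 2, 3, 3, 2, 2, 3),
    S = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
)
rownames(.RESIDUE_TABLE) <- .RESIDUE_TABLE$code

# the 20-letter alphabet, alphabetical: the fixed ordering of the AAC block
.AA_ALPHABET <- .RESIDUE_TABLE$code

# fixed ordering of the atomic-composition block
.ELEMENTS <- c("C", "H", "N", "O", "S")
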