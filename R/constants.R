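# Shared amino-acid constants used across modules.

# The 20 standard amino acids, one-letter code, alphabetical.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy index; drives the synthetic solvation term and
# the mutation-type classification of the generator.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

CHARGED_AA <- c("D", "E", "K", "R", "H")
BULKY_HYDROPHOBIC_AA <- c("F", "W", "Y", "L", "I", "M")

#' Reference residues and codons of the BRAF hydrophobic pocket
#'
#' The 14 positions analysed throughout the package: the N-lobe residues
#' lining the pocket (Phe468, Leu485, Val487, Ala497, Phe498, Leu525), the
#' activation-segment pocket residues (Leu597, Ala598, Trp604) and the
#' intervening segment positions Thr599, Val600, Lys601, Ser602, Arg603.
#' Codons are the human BRAF reference codons where the literature pins them
#' down by printed substitution distances (Val600 = GTG, Leu597 = CTG) and
#' common human codons consistent with those distances elsewhere; the whole
#' mapping is a default, not a constraint — any `position/wt_aa/codon`
#' data frame can be passed to [accessibility_table()].
#'
#' @return A data.frame with columns `position` (integer, BRAF kinase-domain
#'   author numbering), `wt_aa` (1-letter) and `codon` (DNA, uppercase).
#' @export
#' @examples
#' braf_pocket_reference()
braf_pocket_reference <- function() {
  data.frame(
    position = c(468L, 485L, 487L, 497L, 498L, 525L, 597L,
                 598L, 599L, 600L, 601L, 602L, 603L, 604L),
    wt_aa = c("F", "L", "V", "A", "F", "L", "L",
              "A", "T", "V", "K", "S", "R", "W"),
    codon = c("TTC", "CTG", "GTG", "GCC", "TTC", "CTG", "CTG",
              "GCC", "ACA", "GTG", "AAG", "TCC", "AGG", "TGG"),
    stringsAsFactors = FALSE
  )
}

# Activation-segment loop interval (Leu597-Gly615).
AS_LOOP_REGION <- 597:615
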