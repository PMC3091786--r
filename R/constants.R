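#' Built-in sequence constants
#'
#' Fixed sequences used throughout the pipeline:
#' \describe{
#'   \item{`B2_TAIL_PEPTIDE`}{The 21-residue C-terminal extension carried by
#'     ORFeome-derived constructs, produced when the insert's stop codon is
#'     replaced by the Gateway B2 recombination sequence and read through
#'     into vector sequence (`PAFLYKVVIIHSSMHLEGPIL`). Its terminal
#'     tripeptide (`PIL`) matches no PDZ-binding consensus class, so
#'     B2-tagged constructs never present a canonical C-terminal ligand.}
#'   \item{`B2_TAIL_NT`}{One fixed codon spelling of `B2_TAIL_PEPTIDE`, used
#'     by the screen simulator when building ORFeome-mode inserts.}
#'   \item{`ATTB1_TAIL`, `ATTB2_TAIL`}{Default Gateway attB1/attB2
#'     recombination tails prepended to cloning primers. Supplied as
#'     configurable defaults, not asserted as ground truth for any
#'     particular study.}
#'   \item{`GAL4_AD_SUFFIX`}{Default 3' terminal 60 nt of the activation
#'     domain open reading frame immediately upstream of the prey insert.
#'     Stored in frame (length a multiple of 3, no internal stop codons), so
#'     the fusion reading frame of a prey insert starts at the first base
#'     after this suffix. Vector-specific; override via the pipeline
#'     config.}
#' }
#'
#' @name pdzome-constants
#' @aliases B2_TAIL_PEPTIDE B2_TAIL_NT ATTB1_TAIL ATTB2_TAIL GAL4_AD_SUFFIX
NULL

#' @export
B2_TAIL_PEPTIDE <- "PAFLYKVVIIHSSMHLEGPIL"

#' @export
B2_TAIL_NT <- paste0(
  "CCAGCTTTCCTTTACAAAGTTGTTATTATTCAC",
  "TCTTCTATGCACCTTGAAGGTCCAATTCTT"
)

#' @export
ATTB1_TAIL <- "GGGGACAAGTTTGTACAAAAAAGCAGGCT"

#' @export
ATTB2_TAIL <- "GGGGACCACTTTGTACAAGAAAGCTGGGT"

#' @export
GAL4_AD_SUFFIX <- "GCTGAATTCCCAGGTATTCTTGAACAACTGCGTGCAATCGGTGATAACTTCGCCCCAGTG"

# Residue sets defining the C-terminal consensus classes.  The position -2
# sets are pairwise disjoint, so at most one class can match any terminus.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_HYDROPHOBIC <- c("Y", "F", "W", "C", "M", "V", "I", "L", "A")
AA_CLASS1_M2 <- c("S", "T")
AA_CLASS3_M2 <- c("D", "E")

#' Default consensus-class motif definitions
#'
#' The three C-terminal consensus classes as position -2 / position 0
#' residue sets (position -1 is unconstrained): class 1 `[ST]X[Phi]`,
#' class 2 `[Phi]X[Phi]`, class 3 `[DE]X[Phi]`, with
#' Phi = \{Y,F,W,C,M,V,I,L,A\}. Returned as a list that can be edited and
#' passed to [classify_cterm()] to support alternative published motif
#' definitions.
#'
#' @return A named list with one element per class, each holding `m2`
#'   (allowed residues at position -2) and `p0` (allowed residues at the
#'   C-terminal position).
#' @export
#' @examples
#' consensus_motifs()[["1"]]
consensus_motifs <- function() {
  list(
    "1" = list(m2 = AA_CLASS1_M2, p0 = AA_HYDROPHOBIC),
    "2" = list(m2 = AA_HYDROPHOBIC, p0 = AA_HYDROPHOBIC),
    "3" = list(m2 = AA_CLASS3_M2, p0 = AA_HYDROPHOBIC)
  )
}
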