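#' Oligonucleotide sequences of the study
#'
#' The DNA strands used by the experiments this package models (5'->3',
#' fluorophore labels omitted): the 63mer used for accumulation imaging, the
#' complementary 24mer FRET pair, and the replication set (51mer template,
#' two 30mer primers with 5'-AAAAA overhangs, 61mer product).
#'
#' @format A named character vector.
#' @export
oligo_sequences <- c(
  dna63   = "CCAGCCTCCAGTGCCTCGTATCATTGTGCCAAAAGGCACAATGATACGAGGCACTGGAGGCTG",
  fret24_1 = "CGTAGTAAATATCTAGCTAAAGTG",
  fret24_2 = "CACTTTAGCTAGATATTTACTACG",
  template51 = "TTAGCAGAGCGAGGTATGTAGGCGGGACGCTCAGTGGAACGAAAACTCACG",
  primer_rev30 = "AAAAACGTGAGTTTTCGTTCCACTGAGCGT",
  primer_fwd30 = "AAAAATTAGCAGAGCGAGGTATGTAGGCGG",
  product61 = "AAAAATTAGCAGAGCGAGGTATGTAGGCGGGACGCTCAGTGGAACGAAAACTCACGTTTTT"
)

#' Reverse complement of a DNA sequence
#'
#' @param seq Character string of A/C/G/T.
#' @return The reverse complement, 5'->3'.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}
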