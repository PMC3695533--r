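#' Canonical human estrogen receptor alpha protein sequence
#'
#' The 595-residue canonical hERa (ESR1, UniProt P03372) amino-acid
#' sequence, bundled as plain-text FASTA for the truncation-mass worked
#' examples: the N-terminal fragment ending after the DNA-binding domain
#' (residues 1-251) and the fragment ending at the ribosome stall site two
#' codons upstream of the quadruplex-encoding region.
#'
#' @return character scalar, the amino-acid sequence.
#' @examples
#' round(peptide_mass(substr(hera_protein(), 1, 251))$average_mass / 1000, 1)
#' @export
hera_protein <- function() {
  path <- system.file("extdata", "hERa_P03372.fasta", package = "quadstall")
  unname(read_protein_fasta(path)[1])
}

#' Stall-site truncation length on a protein
#'
#' Position of the last residue translated before a ribosome stall six
#' nucleotides (two codons) upstream of a quadruplex-encoding region:
#' locates the peptide motif encoded by the quadruplex and steps back two
#' residues further.
#'
#' @param protein amino-acid string.
#' @param motif peptide motif encoded by the quadruplex region (default the
#'   hERa hinge motif `GEGRGEVGS`).
#' @return integer residue count of the stall-truncated product.
#' @export
stall_truncation_length <- function(protein, motif = "GEGRGEVGS") {
  at <- regexpr(motif, protein, fixed = TRUE)
  if (at < 0)
    stop_quadstall("quadruplex-encoded motif not found in protein",
                   "quadstall_bad_input")
  as.integer(at) - 1L - 2L
}
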