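#' Antisense primers carrying the QFP sequence variants
#'
#' The five 69-nt antisense PCR primers used to build reporter mRNAs
#' carrying the wild-type and the four synonymous mutant
#' quadruplex-forming-potential (QFP) windows from the human estrogen
#' receptor alpha coding region, plus the 49-nt first-round template.
#' Reverse-complementing a primer yields the sense-strand window analysed
#' by [scan_qfp()] and [check_synonymy()].
#'
#' @return named list of DNA [nucleic_seq]: `wild_type`, `A_mutant`,
#'   `C_mutant`, `G_mutant`, `U_mutant`.
#' @examples
#' w <- reverse_complement(qfp_primers()$wild_type)
#' grepl("GGGGAGGGCAGGGGTGAAGTGGGG", as.character(w))
#' @export
qfp_primers <- function() {
  p <- c(
    wild_type = "TTTTTTAGACCCCACTTCACCCCTGCCCTCCCCATCTTTACCTAAATGAATTTTTTTATTAATAAATAA",
    A_mutant  = "TTTTTTAGATCCTACTTCACCTCTGCCTTCTCCATCTTTACCTAAATGAATTTTTTTATTAATAAATAA",
    C_mutant  = "TTTTTTAGACCCGACTTCACCCCTGCCCTCCCCATCTTTACCTAAATGAATTTTTTTATTAATAAATAA",
    G_mutant  = "TTTTTTAGACCCCACTTCCCCCCTCCCCTCCCCATCTTTACCTAAATGAATTTTTTTATTAATAAATAA",
    U_mutant  = "TTTTTTAGAACCAACTTCACCCCTGCCCTCACCATCTTTACCTAAATGAATTTTTTTATTAATAAATAA")
  out <- lapply(names(p), function(nm)
    nucleic_seq(p[[nm]], id = nm, alphabet = "DNA",
                strand_note = "antisense primer"))
  names(out) <- names(p)
  out
}

#' @rdname qfp_primers
#' @export
first_template <- function() {
  nucleic_seq("TAAATGAATTTTTTTATTAATAAATAAGATTTCATAGAAAGCATTTTGT",
              id = "first_template", alphabet = "DNA",
              strand_note = "49-nt first-round PCR template")
}

#' Sense-strand QFP windows derived from the printed primers
#'
#' Reverse complements of [qfp_primers()]: the sense-strand 69-nt windows
#' in which the G-rich tract, reading frame and synonymy are analysed.
#'
#' @return named list of DNA [nucleic_seq].
#' @export
qfp_sense_windows <- function() {
  lapply(qfp_primers(), reverse_complement)
}
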