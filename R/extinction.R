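## Nearest-neighbour molar extinction coefficients at 260 nm for RNA,
## L mol^-1 cm^-1, from Cantor, Warshaw & Shapiro (1970) Biopolymers 9:1059
## (the mononucleotide/dinucleotide table in universal use for oligo
## quantitation). Values are the usual x10^3 entries expanded to full units.
.eps_mono_rna <- c(A = 15400, C = 7200, G = 11500, U = 9900)
.eps_nn_rna <- c(
  AA = 27400, AC = 21200, AG = 25000, AU = 24000,
  CA = 21000, CC = 14200, CG = 17800, CU = 16200,
  GA = 25200, GC = 17400, GG = 21600, GU = 20000,
  UA = 24600, UC = 17200, UG = 20000, UU = 19600)

#' Nearest-neighbour extinction coefficient at 260 nm
#'
#' Computes the molar extinction coefficient of an RNA oligonucleotide from
#' mononucleotide and dinucleotide data by the nearest-neighbour
#' approximation:
#' \deqn{\epsilon = \sum_{i=1}^{n-1} 2\,\epsilon_{NN}(b_i b_{i+1})
#'       - \sum_{i=2}^{n-1} \epsilon_{mono}(b_i)}
#' A length-1 sequence returns the mononucleotide coefficient.
#'
#' @param seq an RNA [nucleic_seq] (a DNA record is transcribed with a
#'   warning-free T to U substitution before lookup).
#' @param table coefficient set; only the bundled `"cantor1970"` RNA table is
#'   provided, but the argument accepts a user list with elements `mono` and
#'   `nn` for alternative published tables.
#' @return extinction coefficient in L mol^-1 cm^-1.
#' @examples
#' extinction_coefficient(nucleic_seq("A", alphabet = "RNA"))   # 15400
#' @export
extinction_coefficient <- function(seq, table = "cantor1970") {
  stopifnot(inherits(seq, "nucleic_seq"))
  if (is.character(table)) {
    table <- match.arg(table, "cantor1970")
    table <- list(mono = .eps_mono_rna, nn = .eps_nn_rna)
  }
  s <- chartr("T", "U", seq$residues)
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  if (n == 1L) return(unname(table$mono[b]))
  pairs <- paste0(b[-n], b[-1L])
  unname(2 * sum(table$nn[pairs]) - sum(table$mono[b[-c(1L, n)]]))
}

## Average residue masses (Da) for the 20 standard amino acids, plus water
## and hydrogen, IUPAC 1997 atomic weights.
.aa_avg_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.mass_water <- 18.01528
.mass_hydrogen <- 1.00794

#' Average peptide mass
#'
#' Sum of average residue masses plus one water; optionally plus one
#' hydrogen for the protonated (MALDI-scale \[M+H\]+) value. Average, not
#' monoisotopic, masses are used so results compare directly with
#' gel/MALDI-scale molecular weights.
#'
#' @param aa_seq character scalar over the 20 standard one-letter codes.
#' @param protonated add one hydrogen.
#' @return list of class `peptide_mass` with `n_residues`, `average_mass`
#'   and `protonated_mass` (Da).
#' @examples
#' peptide_mass("G")$average_mass   # 75.07, free glycine
#' @export
peptide_mass <- function(aa_seq, protonated = FALSE) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  aa_seq <- toupper(gsub("[[:space:]*]", "", aa_seq))
  if (nchar(aa_seq) == 0L)
    stop_quadstall("empty peptide", "quadstall_bad_sequence")
  res <- strsplit(aa_seq, "")[[1]]
  m <- .aa_avg_mass[res]
  if (anyNA(m))
    stop_quadstall(sprintf("unknown residue '%s'",
                           res[which(is.na(m))[1]]),
                   "quadstall_bad_sequence")
  avg <- sum(m) + .mass_water
  structure(list(n_residues = length(res), average_mass = avg,
                 protonated_mass = avg + .mass_hydrogen,
                 protonated = protonated),
            class = "peptide_mass")
}

#' @export
print.peptide_mass <- function(x, ...) {
  cat(sprintf("peptide of %d residues: average mass %.1f Da (%.1f Da [M+H]+)\n",
              x$n_residues, x$average_mass, x$protonated_mass))
  invisible(x)
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings that return or accept [nucleic_seq]
#' lists; the input alphabet (T vs U) is preserved on output.
#'
#' @param path file path.
#' @return `read_fasta`: a named list of [nucleic_seq].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(set), function(i)
    nucleic_seq(as.character(set[[i]]), id = names(set)[i]))
  names(out) <- names(set)
  out
}

#' @param seqs a [nucleic_seq] or list of them.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nucleic_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein FASTA as plain amino-acid strings
#'
#' @param path file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
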