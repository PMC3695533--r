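#' Nucleic-acid sequence with alphabet metadata
#'
#' A light container for a single DNA or RNA sequence. The alphabet is
#' inferred from the residues when not given (presence of U implies RNA, of T
#' implies DNA; a sequence with neither defaults to DNA). Mixing T and U in
#' one record is rejected.
#'
#' @param residues character scalar over A, C, G, T, U (case-insensitive).
#' @param id text label.
#' @param alphabet "DNA" or "RNA"; inferred when `NULL`.
#' @param strand_note free-text strand annotation carried through untouched.
#' @return An object of class `nucleic_seq` with fields `id`, `residues`,
#'   `alphabet`, `strand_note`.
#' @examples
#' nucleic_seq("GGGGAGGGCAGGGG", id = "qfp")
#' @export
nucleic_seq <- function(residues, id = "seq", alphabet = NULL,
                        strand_note = "") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) == 0L)
    stop_quadstall("empty sequence", "quadstall_bad_sequence")
  bad <- regmatches(residues, regexpr("[^ACGTU]", residues))
  if (length(bad) && nzchar(bad)) {
    pos <- regexpr("[^ACGTU]", residues)
    stop_quadstall(sprintf("unknown base '%s' at position %d", bad, pos),
                   "quadstall_bad_sequence")
  }
  has_t <- grepl("T", residues, fixed = TRUE)
  has_u <- grepl("U", residues, fixed = TRUE)
  if (has_t && has_u)
    stop_quadstall("sequence mixes T and U", "quadstall_bad_sequence")
  if (is.null(alphabet)) alphabet <- if (has_u) "RNA" else "DNA"
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  if (alphabet == "DNA" && has_u)
    stop_quadstall("U in a DNA record", "quadstall_bad_sequence")
  if (alphabet == "RNA" && has_t)
    stop_quadstall("T in an RNA record", "quadstall_bad_sequence")
  structure(list(id = id, residues = residues, alphabet = alphabet,
                 strand_note = strand_note),
            class = "nucleic_seq")
}

#' @export
print.nucleic_seq <- function(x, ...) {
  cat(sprintf("<nucleic_seq %s> %s, %d nt\n", x$id, x$alphabet,
              nchar(x$residues)))
  cat(x$residues, "\n")
  invisible(x)
}

#' @export
as.character.nucleic_seq <- function(x, ...) x$residues

as_dna_string <- function(x) chartr("U", "T", x$residues)

#' Reverse complement
#'
#' Watson-Crick complement in reverse order; the alphabet is preserved
#' (DNA in, DNA out). Needed to recover sense quadruplex windows from
#' antisense PCR primers.
#'
#' @param seq a [nucleic_seq].
#' @return a [nucleic_seq] on the opposite strand.
#' @examples
#' as.character(reverse_complement(nucleic_seq("ACGT")))  # "ACGT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "nucleic_seq"))
  rc <- if (seq$alphabet == "DNA") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq$residues)))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq$residues)))
  }
  nucleic_seq(rc, id = paste0(seq$id, "_rc"), alphabet = seq$alphabet,
              strand_note = paste("reverse complement of", seq$id))
}

#' Transcribe a DNA record to RNA (T to U; same strand)
#'
#' @param seq a DNA [nucleic_seq].
#' @return an RNA [nucleic_seq].
#' @export
transcribe <- function(seq) {
  stopifnot(inherits(seq, "nucleic_seq"))
  nucleic_seq(chartr("T", "U", seq$residues), id = seq$id, alphabet = "RNA",
              strand_note = seq$strand_note)
}

#' Translate a nucleic-acid sequence
#'
#' Standard genetic code, RNA or DNA accepted (T and U equivalent). A
#' trailing partial codon is dropped; stop codons render as `*` and
#' translation continues through them (the windows analysed here are
#' sub-genic and need not start at an AUG).
#'
#' @param seq a [nucleic_seq].
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return character scalar of amino acids.
#' @examples
#' translate_seq(nucleic_seq("AUGUUU"))  # "MF"
#' @export
translate_seq <- function(seq, frame = 0) {
  stopifnot(inherits(seq, "nucleic_seq"), frame %in% 0:2)
  s <- as_dna_string(seq)
  n <- nchar(s) - frame
  if (n < 3L)
    stop_quadstall("sequence shorter than one codon in this frame",
                   "quadstall_bad_frame")
  n_codon <- n %/% 3L
  starts <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa))
    stop_quadstall("untranslatable codon", "quadstall_bad_sequence")
  paste(aa, collapse = "")
}

#' Check synonymy of aligned variant windows against a reference
#'
#' Translates equal-length aligned windows in the given frame and reports,
#' per variant, how many codons differ at the nucleotide level and whether
#' the encoded amino-acid strings are identical.
#'
#' @param ref reference [nucleic_seq].
#' @param variants list of [nucleic_seq] of the same length as `ref`.
#' @param frame reading-frame offset shared by all windows.
#' @return data.frame with columns `id`, `n_codons_changed`, `is_synonymous`.
#' @export
check_synonymy <- function(ref, variants, frame = 0) {
  stopifnot(inherits(ref, "nucleic_seq"))
  if (inherits(variants, "nucleic_seq")) variants <- list(variants)
  ref_aa <- translate_seq(ref, frame)
  ref_dna <- as_dna_string(ref)
  out <- lapply(variants, function(v) {
    stopifnot(inherits(v, "nucleic_seq"))
    if (nchar(v$residues) != nchar(ref$residues))
      stop_quadstall("variant length differs from reference",
                     "quadstall_bad_alignment")
    v_dna <- as_dna_string(v)
    n <- nchar(ref_dna) - frame
    n_codon <- n %/% 3L
    starts <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
    changed <- sum(substring(ref_dna, starts, starts + 2L) !=
                   substring(v_dna, starts, starts + 2L))
    data.frame(id = v$id, n_codons_changed = changed,
               is_synonymous = identical(translate_seq(v, frame), ref_aa))
  })
  do.call(rbind, out)
}

#' Find the reading frame under which all variants are synonymous
#'
#' Tries frames 0, 1 and 2 and returns the first in which every variant
#' translation equals the reference translation. Used for primer-derived
#' windows whose frame is not recorded in machine-readable form.
#'
#' @inheritParams check_synonymy
#' @return integer frame offset, or an error if no frame works.
#' @export
find_synonymous_frame <- function(ref, variants) {
  for (f in 0:2) {
    rep <- tryCatch(check_synonymy(ref, variants, frame = f),
                    error = function(e) NULL)
    if (!is.null(rep) && all(rep$is_synonymous)) return(f)
  }
  stop_quadstall("no frame renders all variants synonymous",
                 "quadstall_no_frame")
}

#' Scan for quadruplex-forming-potential (QFP) sequence
#'
#' Greedy left-to-right scan of the given strand for runs of at least four
#' G-tracts (maximal runs of G of length >= `min_tract`) separated by loops
#' whose lengths lie within `[loop_min, loop_max]`. Each reported hit is a
#' maximal window: the chain of tracts is extended as far as loop bounds
#' allow, and scanning resumes after the window. Coordinates are 0-based,
#' half-open, on the scanned strand only.
#'
#' @param seq a [nucleic_seq].
#' @param min_tract minimum G-run length counting as a tract (>= 2). The
#'   permissive default 2 admits mixed-tetrad candidates; use 3 for the
#'   strict canonical contrast.
#' @param loop_min,loop_max inclusive loop-length bounds.
#' @return list of hits, each a list with `start`, `end`, `tracts`
#'   (data.frame `start`, `length`), `loop_lengths`, `min_tract`. Empty list
#'   when nothing qualifies.
#' @examples
#' w <- nucleic_seq("GGGGAGGGCAGGGGTGAAGTGGGG")
#' length(scan_qfp(w, min_tract = 3))  # 1
#' @export
scan_qfp <- function(seq, min_tract = 2, loop_min = 1, loop_max = 7) {
  stopifnot(inherits(seq, "nucleic_seq"), min_tract >= 2,
            loop_min >= 0, loop_max >= loop_min)
  s <- seq$residues
  m <- gregexpr(sprintf("G{%d,}", min_tract), s)[[1]]
  if (m[1] == -1L) return(list())
  run_start <- as.integer(m) - 1L                 # 0-based
  run_len <- attr(m, "match.length")
  run_end <- run_start + run_len                  # half-open
  hits <- list()
  i <- 1L
  n_run <- length(run_start)
  while (i <= n_run) {
    j <- i
    while (j < n_run) {
      loop <- run_start[j + 1L] - run_end[j]
      if (loop >= loop_min && loop <= loop_max) j <- j + 1L else break
    }
    if (j - i + 1L >= 4L) {
      idx <- i:j
      hits[[length(hits) + 1L]] <- list(
        start = run_start[i], end = run_end[j],
        tracts = data.frame(start = run_start[idx], length = run_len[idx]),
        loop_lengths = run_start[idx[-1L]] - run_end[idx[-length(idx)]],
        min_tract = min_tract)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  hits
}
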