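test_that("reverse complement is a palindromic-safe involution", {
  expect_equal(as.character(reverse_complement(nucleic_seq("ACGT"))), "ACGT")
  set.seed(11)
  for (i in 1:20) {
    s <- nucleic_seq(random_rna(sample(5:40, 1)))
    expect_equal(as.character(reverse_complement(reverse_complement(s))),
                 as.character(s))
  }
  expect_error(nucleic_seq("ACGX"), class = "quadstall_bad_sequence")
  expect_error(nucleic_seq("ACGTU"), class = "quadstall_bad_sequence")
})

test_that("wild-type antisense primer yields the expected sense quadruplex window", {
  w <- reverse_complement(qfp_primers()$wild_type)
  expect_true(grepl("GGGGAGGGCAGGGGTGAAGTGGGG", as.character(w), fixed = TRUE))
  expect_equal(w$alphabet, "DNA")
})

test_that("translation follows the standard code and drops partial codons", {
  expect_equal(translate_seq(nucleic_seq("AUGUUU")), "MF")
  expect_equal(translate_seq(nucleic_seq("ATGTTTA")), "MF")  # partial dropped
  expect_equal(translate_seq(nucleic_seq("AUGUAA")), "M*")
  expect_equal(translate_seq(nucleic_seq("GAUGUUU"), frame = 1), "MF")
  expect_error(translate_seq(nucleic_seq("AU")), class = "quadstall_bad_frame")
  # length law on stop-free sequences
  set.seed(7)
  for (i in 1:10) {
    n <- sample(6:30, 1); f <- sample(0:2, 1)
    s <- nucleic_seq(paste(rep("GCA", 12), collapse = ""))
    expect_equal(nchar(translate_seq(s, f)), (36 - f) %/% 3)
  }
})

test_that("all printed mutant windows are synonymous with wild-type in frame 0", {
  w <- qfp_sense_windows()
  expect_equal(find_synonymous_frame(w$wild_type, w[-1]), 0)
  rep <- check_synonymy(w$wild_type, w[-1], frame = 0)
  expect_true(all(rep$is_synonymous))
  expect_true(all(rep$n_codons_changed > 0))
  self <- check_synonymy(w$wild_type, w["wild_type"], frame = 0)
  expect_equal(self$n_codons_changed, 0)
  expect_true(self$is_synonymous)
  # single synonymous codon change (Gly is 4-fold degenerate)
  rep2 <- check_synonymy(nucleic_seq("GGG"), list(nucleic_seq("GGA")), 0)
  expect_equal(rep2$n_codons_changed, 1)
  expect_true(rep2$is_synonymous)
  expect_error(check_synonymy(nucleic_seq("GGG"), list(nucleic_seq("GGGG"))),
               class = "quadstall_bad_alignment")
})

test_that("QFP scanner separates wild-type from the quadruplex-free mutant", {
  w <- qfp_sense_windows()
  hits <- scan_qfp(w$wild_type, min_tract = 3)
  expect_length(hits, 1)
  expect_gte(nrow(hits[[1]]$tracts), 4)
  expect_true(all(hits[[1]]$tracts$length >= 3))
  expect_true(all(hits[[1]]$loop_lengths >= 1 & hits[[1]]$loop_lengths <= 7))
  expect_length(scan_qfp(w$A_mutant, min_tract = 3), 0)
  expect_length(scan_qfp(nucleic_seq("GGGG"), min_tract = 2), 0)
  # permissive default admits the U-mutant's mixed-tetrad candidate
  expect_gte(length(scan_qfp(w$U_mutant, min_tract = 2)), 1)
})

test_that("QFP scanner agrees with a regex-free character-walk enumerator", {
  set.seed(42)
  for (i in 1:300) {
    s <- random_rna(sample(12:20, 1), g_rich = TRUE)
    mt <- sample(2:3, 1)
    got <- scan_qfp(nucleic_seq(s), min_tract = mt)
    want <- bf_scan_qfp(s, min_tract = mt)
    expect_length(got, length(want))
    if (length(got)) {
      for (h in seq_along(got)) {
        expect_equal(got[[h]]$start, unname(want[[h]]["start"]))
        expect_equal(got[[h]]$end, unname(want[[h]]["end"]))
        expect_true(all(got[[h]]$tracts$length >= mt))
      }
    }
  }
})

test_that("nearest-neighbour extinction coefficients match direct evaluation", {
  expect_equal(extinction_coefficient(nucleic_seq("A", alphabet = "RNA")), 15400)
  expect_equal(extinction_coefficient(nucleic_seq("AA")), 2 * 27400)
  wt_rna <- transcribe(reverse_complement(qfp_primers()$wild_type))
  expect_equal(extinction_coefficient(wt_rna),
               bf_extinction(as.character(wt_rna)))
  set.seed(3)
  for (i in 1:100) {
    s <- random_rna(sample(1:60, 1))
    expect_equal(extinction_coefficient(nucleic_seq(s, alphabet = "RNA")),
                 bf_extinction(s))
  }
})

test_that("peptide masses use average residue masses plus water", {
  g <- peptide_mass("G")
  expect_equal(g$average_mass, 75.07, tolerance = 1e-4)
  expect_equal(g$protonated_mass - g$average_mass, 1.00794)
  expect_error(peptide_mass(""), class = "quadstall_bad_sequence")
  expect_error(peptide_mass("GB"), class = "quadstall_bad_sequence")
  # additivity
  expect_equal(peptide_mass("GAVL")$average_mass,
               sum(peptide_mass("G")$average_mass,
                   peptide_mass("A")$average_mass,
                   peptide_mass("V")$average_mass,
                   peptide_mass("L")$average_mass) - 3 * 18.01528,
               tolerance = 1e-8)
})

test_that("FASTA round-trips preserve residues and alphabet", {
  tmp <- tempfile(fileext = ".fasta")
  seqs <- list(nucleic_seq("ACGTACGTACGT", id = "dna1"),
               nucleic_seq("ACGUACGU", id = "rna1"))
  write_fasta(seqs, tmp)
  back <- read_fasta(tmp)
  expect_equal(as.character(back$dna1), "ACGTACGTACGT")
  expect_equal(back$rna1$alphabet, "RNA")
})
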