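# Independent oracles used to freeze expected values; these deliberately
# avoid the code paths they check.

# character-walk G-run finder + block chaining (no regex), mirroring the
# scanner's declared semantics for equivalence testing
bf_scan_qfp <- function(s, min_tract = 2, loop_min = 1, loop_max = 7) {
  b <- strsplit(s, "")[[1]]
  runs <- list()
  i <- 1L
  while (i <= length(b)) {
    if (b[i] == "G") {
      j <- i
      while (j < length(b) && b[j + 1L] == "G") j <- j + 1L
      if (j - i + 1L >= min_tract)
        runs[[length(runs) + 1L]] <- c(start = i - 1L, len = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(list())
  runs <- do.call(rbind, runs)
  hits <- list()
  i <- 1L
  while (i <= nrow(runs)) {
    j <- i
    while (j < nrow(runs)) {
      gap <- runs[j + 1L, "start"] - (runs[j, "start"] + runs[j, "len"])
      if (gap >= loop_min && gap <= loop_max) j <- j + 1L else break
    }
    if (j - i + 1L >= 4L)
      hits[[length(hits) + 1L]] <-
        c(start = unname(runs[i, "start"]),
          end = unname(runs[j, "start"] + runs[j, "len"]),
          n_tracts = j - i + 1L)
    i <- j + 1L
  }
  hits
}

# position-by-position spreadsheet-style evaluation of the nearest-neighbour
# extinction formula over the same bundled table
bf_extinction <- function(s) {
  mono <- c(A = 15400, C = 7200, G = 11500, U = 9900)
  nn <- c(AA = 27400, AC = 21200, AG = 25000, AU = 24000,
          CA = 21000, CC = 14200, CG = 17800, CU = 16200,
          GA = 25200, GC = 17400, GG = 21600, GU = 20000,
          UA = 24600, UC = 17200, UG = 20000, UU = 19600)
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  if (n == 1L) return(unname(mono[b]))
  tot <- 0
  for (i in seq_len(n - 1L)) tot <- tot + 2 * nn[paste0(b[i], b[i + 1L])]
  if (n > 2L) for (i in 2:(n - 1L)) tot <- tot - mono[b[i]]
  unname(tot)
}

random_rna <- function(n, g_rich = FALSE) {
  p <- if (g_rich) c(0.15, 0.15, 0.55, 0.15) else rep(0.25, 4)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = p),
        collapse = "")
}

table1_rows <- data.frame(
  name = c("wild_type", "C_mutant", "G_mutant", "U_mutant"),
  dG37 = c(-5.15, -4.77, -5.86, -0.47),
  Tm_C = c(76.4, 72.6, 82.4, 39.9))
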