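# Independent oracles, written as direct loops/regex scans so they share no
# code path with the implementation they check.

# Brute-force PWM-M tabulation: one explicit loop over windows and offsets.
oracle_pwm_m <- function(windows) {
  N <- nrow(windows)
  w <- nchar(windows$seq[1])
  M <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), seq.int(-(w - 1) / 2, (w - 1) / 2)))
  for (k in seq_len(N)) {
    ch <- strsplit(windows$seq[k], "")[[1]]
    for (j in seq_len(w)) {
      M[ch[j], j] <- M[ch[j], j] + windows$m[k]
    }
  }
  M / N
}

.iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                  S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                  D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(motif) {
  paste(.iupac_regex[strsplit(motif, "")[[1]]], collapse = "")
}

# Overlap-permitting regex scan for a motif's target cytosines on both
# strands; returns data.frame(pos, strand) of 1-based target positions.
oracle_motif_targets <- function(seq_chr, motif, target_offset) {
  rx <- paste0("(?=", iupac_to_regex(motif), ")")
  n <- nchar(seq_chr)
  L <- nchar(motif)
  scan <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  plus <- scan(seq_chr) + target_offset
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
  q <- scan(rc)                      # starts on the reverse-complement string
  minus <- n - (q + target_offset) + 1L
  rbind(
    data.frame(pos = plus, strand = rep("+", length(plus))),
    data.frame(pos = minus, strand = rep("-", length(minus)))
  )
}

# random windows for oracle-equivalence tests
random_windows <- function(n, l = 3L, seed = 1L) {
  set.seed(seed)
  w <- 2L * l + 1L
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    s[l + 1L] <- "C"
    paste(s, collapse = "")
  }, character(1))
  data.frame(seq = seqs, m = stats::runif(n), depth = 10L,
             stringsAsFactors = FALSE)
}

as_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(setNames(seqs, names(seqs)))
}

write_fasta_tmp <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
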