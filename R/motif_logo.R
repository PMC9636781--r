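# Methylation-weighted PWM (PWM-M), M-logo, and IUPAC consensus calling.
#
# The statistic: every cytosine k with methylation level m_k contributes its
# +/- l sequence neighbourhood as a window; for base i at offset j,
#     M_ij = (1/N) * sum_k m_k * I_i(S_{K+j})
# where N is the number of contributing windows. Normalising per offset,
#     f_ij = M_ij / sum_i M_ij,
# gives a frequency profile weighted by methylation, from which the logo
#     H_j = -sum_i f_ij log2 f_ij,   R_j = log2(4) - H_j - 0.541,
#     height_ij = f_ij * R_j
# is computed. Offsets enriched for specific bases among highly methylated
# windows stand out with large R_j; the consensus caller collapses them to
# an IUPAC recognition sequence.

BASES <- c("A", "C", "G", "T")

#' Extract methylation-weighted sequence windows
#'
#' For every cytosine record with read depth at least `min_depth`, takes the
#' genomic subsequence of length `2l + 1` centred on the cytosine. Records on
#' the minus strand yield the reverse complement of the genomic slice, so the
#' centre base is always `C` and offsets read 5'->3' on the methylated
#' strand. Windows truncated by a contig edge or containing `N`, and records
#' with zero total reads, are skipped.
#'
#' @param genome genome as from [read_genome()].
#' @param records a `cytosine_report`.
#' @param l half-width of the window in bp (window length `2l + 1`).
#' @param min_depth minimum read depth for a record to contribute.
#' @return a `data.frame` with columns `seq` (window string), `m`
#'   (methylation level) and `depth`.
#' @export
extract_windows <- function(genome, records, l = 5L, min_depth = 5L) {
  stopifnot(l >= 1L)
  g <- genome_chars(genome)
  unknown <- setdiff(unique(records$contig), names(g))
  if (length(unknown)) stop("records reference unknown contig(s): ",
                            paste(unknown, collapse = ", "))
  len <- nchar(g)[records$contig]
  oob <- which(records$pos < 1L | records$pos > len)
  if (length(oob)) {
    stop("record ", oob[1], " (", records$contig[oob[1]], ":",
         records$pos[oob[1]], ") is outside its contig")
  }
  tot <- records$meth + records$unmeth
  keep <- tot > 0L & tot >= min_depth &
    records$pos - l >= 1L & records$pos + l <= len
  if (!any(keep)) {
    return(data.frame(seq = character(0), m = numeric(0), depth = integer(0)))
  }
  rec <- records[keep, , drop = FALSE]
  seqs <- substring(g[rec$contig], rec$pos - l, rec$pos + l)
  minus <- rec$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  ok <- !grepl("N", seqs, fixed = TRUE)
  rec <- rec[ok, , drop = FALSE]
  data.frame(
    seq = seqs[ok],
    m = rec$meth / (rec$meth + rec$unmeth),
    depth = rec$meth + rec$unmeth,
    stringsAsFactors = FALSE
  )
}

#' Compute the methylation-weighted position weight matrix (PWM-M)
#'
#' For windows `k = 1..N` with methylation level `m_k`,
#' `M[i, j] = sum_k m_k * I(base at offset j is i) / N`, and the normalised
#' methylation-weighted frequency is `f[i, j] = M[i, j] / sum_i M[i, j]`.
#' Offsets with a zero column sum (no methylation signal at all) are flagged
#' degenerate and carry `f = 0`.
#'
#' @param windows as returned by [extract_windows()].
#' @return an object of class `pwmm`: list with `l`, `N`, matrices `M` and
#'   `f` (rows A/C/G/T, columns offsets `-l..l`), and logical `degenerate`
#'   per offset.
#' @export
compute_pwm_m <- function(windows) {
  N <- nrow(windows)
  if (is.null(N) || N < 1L) stop("no windows: cannot compute PWM-M")
  w <- nchar(windows$seq[1])
  if (any(nchar(windows$seq) != w)) stop("windows must all have equal length")
  l <- (w - 1L) %/% 2L
  offsets <- seq.int(-l, l)
  M <- matrix(0, nrow = 4L, ncol = w, dimnames = list(BASES, offsets))
  m <- windows$m
  for (jj in seq_len(w)) {
    b <- substr(windows$seq, jj, jj)
    bf <- factor(b, levels = BASES)
    M[, jj] <- vapply(split(m, bf), sum, numeric(1)) / N
  }
  colsum <- colSums(M)
  degenerate <- colsum == 0
  f <- M
  nz <- which(!degenerate)
  f[, nz] <- sweep(M[, nz, drop = FALSE], 2L, colsum[nz], "/")
  f[, degenerate] <- 0
  structure(list(l = l, N = N, M = M, f = f, degenerate = degenerate),
            class = "pwmm")
}

#' Compute the M-logo table from a PWM-M
#'
#' Per offset `j`: Shannon entropy `H_j = -sum_i f_ij log2 f_ij` (with
#' `0 log 0 := 0`), information content `R_j = log2(4) - H_j - 0.541`, and
#' letter heights `height_ij = f_ij * R_j`. The 0.541 term is a fixed
#' small-sample constant; `R_j` is not clamped, so uninformative offsets can
#' carry negative information content. Degenerate offsets carry `H = NA` and
#' are excluded from consensus calling.
#'
#' @param p a `pwmm`.
#' @return an object of class `logo_table`: list with numeric vectors `H`,
#'   `R` (named by offset), matrix `heights`, and `degenerate`.
#' @export
compute_logo <- function(p) {
  stopifnot(inherits(p, "pwmm"))
  f <- p$f
  plogp <- f * log2(f)
  plogp[f == 0] <- 0
  H <- -colSums(plogp)
  H[p$degenerate] <- NA_real_
  R <- 2 - H - 0.541
  heights <- sweep(f, 2L, R, "*")
  heights[, p$degenerate] <- NA_real_
  structure(list(H = H, R = R, heights = heights, degenerate = p$degenerate),
            class = "logo_table")
}

#' Collapse an M-logo to an IUPAC consensus recognition sequence
#'
#' The consensus span is the minimal contiguous offset interval containing
#' the central cytosine (offset 0) and every offset with information content
#' `R_j >= theta`. Within the span, offsets below `theta` become `N`; at
#' informative offsets, bases are accumulated in decreasing `f_ij` until the
#' cumulative frequency reaches `kappa` (ties at the cutoff are all
#' included), and the resulting base set is written as its IUPAC code.
#'
#' @param logo a `logo_table`.
#' @param p the matching `pwmm`.
#' The default `theta` of 0.05 bits is calibrated against the statistic's
#' own scale: offsets carrying no recognition signal sit near
#' `R = 2 - 2 - 0.541 = -0.541` bits, while even a heavily
#' background-diluted informative offset (a rare 4-bp motif at ~1.5%
#' target density among cytosines) stays above ~0.1 bits, so a small
#' positive threshold separates them with a wide margin.
#'
#' @param theta information-content threshold in bits (`> 0`).
#' @param kappa cumulative-frequency cutoff (`0.5 < kappa <= 1`).
#' @return an object of class `consensus_motif`: list with `iupac`,
#'   `target_index` (0-based index of the methylated C), `theta`, `kappa`.
#' @export
call_consensus <- function(logo, p, theta = 0.05, kappa = 0.85) {
  stopifnot(inherits(logo, "logo_table"), inherits(p, "pwmm"))
  if (theta <= 0) stop("theta must be positive")
  if (kappa <= 0.5 || kappa > 1) stop("kappa must be in (0.5, 1]")
  if (all(logo$degenerate)) stop("logo is fully degenerate: no methylation signal")
  offsets <- as.integer(colnames(p$f))
  informative <- !logo$degenerate & !is.na(logo$R) & logo$R >= theta
  center <- which(offsets == 0L)
  if (!length(center)) stop("logo has no central offset")
  idx <- which(informative)
  span <- range(c(center, idx))
  out <- character(0)
  for (jj in seq.int(span[1], span[2])) {
    if (!informative[jj]) {
      out <- c(out, "N")
      next
    }
    fr <- sort(p$f[, jj], decreasing = TRUE)
    cum <- cumsum(fr)
    ncut <- which(cum >= kappa - 1e-12)[1]
    # include all bases tied with the last one admitted
    sel <- fr >= fr[ncut] - 1e-12
    out <- c(out, iupac_code(names(fr)[sel]))
  }
  # span is minimal so its endpoints are informative (or the centre);
  # stripping is a no-op unless the centre itself bounds the span.
  while (length(out) > 1 && out[1] == "N") { out <- out[-1]; span[1] <- span[1] + 1L }
  while (length(out) > 1 && out[length(out)] == "N") { out <- out[-length(out)]; span[2] <- span[2] - 1L }
  target_index <- center - span[1]
  structure(list(iupac = paste(out, collapse = ""),
                 target_index = as.integer(target_index),
                 theta = theta, kappa = kappa),
            class = "consensus_motif")
}

#' End-to-end recognition-sequence determination
#'
#' Composes [extract_windows()], [compute_pwm_m()], [compute_logo()] and
#' [call_consensus()]: from a genome and a per-cytosine methylation report to
#' the IUPAC recognition sequence of the methyltransferase that produced the
#' methylation pattern.
#'
#' @inheritParams extract_windows
#' @inheritParams call_consensus
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.pwm.tsv` (M and f), `<prefix>.logo.tsv` (H, R, heights) and
#'   `<prefix>.motif.txt` (IUPAC string and target index).
#' @return list with elements `motif` (`consensus_motif`), `logo`
#'   (`logo_table`), `pwm` (`pwmm`) and `n_windows`.
#' @export
recognition_pipeline <- function(genome, records, l = 5L, min_depth = 5L,
                                 theta = 0.05, kappa = 0.85,
                                 out_prefix = NULL) {
  windows <- extract_windows(genome, records, l = l, min_depth = min_depth)
  pwm <- compute_pwm_m(windows)
  logo <- compute_logo(pwm)
  motif <- call_consensus(logo, pwm, theta = theta, kappa = kappa)
  if (!is.null(out_prefix)) {
    pw <- data.frame(offset = rep(as.integer(colnames(pwm$M)), each = 4L),
                     base = rep(BASES, ncol(pwm$M)),
                     M = as.vector(pwm$M), f = as.vector(pwm$f))
    utils::write.table(pw, paste0(out_prefix, ".pwm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    lg <- data.frame(offset = as.integer(colnames(pwm$M)),
                     H = logo$H, R = logo$R, t(logo$heights))
    names(lg)[4:7] <- paste0("height_", BASES)
    utils::write.table(lg, paste0(out_prefix, ".logo.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(sprintf("%s\t%d", motif$iupac, motif$target_index),
               paste0(out_prefix, ".motif.txt"))
  }
  list(motif = motif, logo = logo, pwm = pwm, n_windows = pwm$N)
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("Consensus recognition sequence:", x$iupac,
      sprintf("(methylated C at index %d; theta = %g bits, kappa = %g)\n",
              x$target_index, x$theta, x$kappa))
  invisible(x)
}

#' @export
print.pwmm <- function(x, ...) {
  cat(sprintf("PWM-M over %d windows, half-width l = %d\n", x$N, x$l))
  print(round(x$f, 3))
  invisible(x)
}
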