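# Cytosine-context classification, motif-target census, analytical
# resolution, and the in-silico methylation-sensitive restriction digest.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify every cytosine by its sequence context
#'
#' Labels every cytosine on both strands with its dinucleotide class (next
#' base: CG/CC/CA/CT) and the derived trinucleotide flags used by NOMe-Seq
#' channel separation: `HCG` (H = A/C/T preceding a CG), `GCG` (the
#' ambiguous overlap of CG-intrinsic and GC-induced methylation), `GCH`
#' (GC followed by A/C/T) and `CCD` (CC followed by A/G/T). All labels are
#' strand-local (read 5'->3' on the strand carrying the cytosine).
#' Cytosines lacking the relevant neighbour (contig edge or `N`) carry `NA`
#' for the affected label.
#'
#' @param genome genome as from [read_genome()].
#' @return `data.frame` with columns `contig`, `pos` (1-based), `strand`,
#'   `dinuc`, and logical `hcg`, `gch`, `gcg`, `ccd`.
#' @export
classify_contexts <- function(genome) {
  g <- genome_chars(genome)
  out <- vector("list", 2L * length(g))
  k <- 0L
  for (ctg in names(g)) {
    ch <- strsplit(g[[ctg]], "")[[1]]
    n <- length(ch)
    at <- function(i) ifelse(i >= 1L & i <= n, ch[pmax(pmin(i, n), 1L)], "N")
    for (std in c("+", "-")) {
      pos <- if (std == "+") which(ch == "C") else which(ch == "G")
      if (!length(pos)) next
      if (std == "+") {
        nxt <- at(pos + 1L); prv <- at(pos - 1L); nx2 <- at(pos + 2L)
      } else {
        nxt <- unname(.COMPLEMENT[at(pos - 1L)])
        prv <- unname(.COMPLEMENT[at(pos + 1L)])
        nx2 <- unname(.COMPLEMENT[at(pos - 2L)])
      }
      h <- c("A", "C", "T")
      dinuc <- ifelse(nxt %in% c("A", "C", "G", "T"), paste0("C", nxt), NA)
      # a flag is NA only when a neighbour it actually depends on is missing
      hcg <- ifelse(nxt == "N", NA,
                    ifelse(nxt != "G", FALSE,
                           ifelse(prv == "N", NA, prv %in% h)))
      gcg <- ifelse(nxt == "N", NA,
                    ifelse(nxt != "G", FALSE,
                           ifelse(prv == "N", NA, prv == "G")))
      gch <- ifelse(nxt == "N", NA,
                    ifelse(!(nxt %in% h), FALSE,
                           ifelse(prv == "N", NA, prv == "G")))
      ccd <- ifelse(nxt == "N", NA,
                    ifelse(nxt != "C", FALSE,
                           ifelse(nx2 == "N", NA, nx2 %in% c("A", "G", "T"))))
      k <- k + 1L
      out[[k]] <- data.frame(
        contig = ctg, pos = pos, strand = std, dinuc = dinuc,
        hcg = hcg, gch = gch, gcg = gcg, ccd = ccd,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res)) {
    res <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), dinuc = character(0),
                      hcg = logical(0), gch = logical(0), gcg = logical(0),
                      ccd = logical(0))
  }
  res <- res[order(res$contig, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# match an IUPAC motif on the plus strand of one contig; returns 1-based
# start positions, with occurrences containing N skipped
.match_motif_starts <- function(seq_chr, motif) {
  subj <- Biostrings::DNAString(seq_chr)
  hits <- Biostrings::matchPattern(motif, subj, fixed = FALSE)
  st <- BiocGenerics::start(hits)
  if (length(st)) {
    frag <- substring(seq_chr, st, st + nchar(motif) - 1L)
    st <- st[!grepl("N", frag, fixed = TRUE)]
  }
  st
}

# 0-based index of the methylated (target) C within a motif: the first
# literal C, the convention used for all built-in recognition sequences
default_target_offset <- function(motif) {
  i <- regexpr("C", motif, fixed = TRUE)
  if (i < 0) stop("motif has no literal C: ", motif)
  as.integer(i) - 1L
}

#' Count a motif's target cytosines genome-wide
#'
#' Counts the target cytosine of every (possibly overlapping) occurrence of
#' an IUPAC motif on both strands. Palindromic motifs therefore count two
#' target cytosines per duplex site, one per strand — the convention that
#' makes the number of methylatable CG cytosines in a genome even.
#' Occurrences containing `N` are skipped.
#'
#' @param genome genome as from [read_genome()].
#' @param motif IUPAC motif string.
#' @param target_offset 0-based index of the methylated C within the motif;
#'   defaults to the first literal `C`.
#' @return list with `n_sites` and `positions` (data.frame of `contig`,
#'   `pos` 1-based position of the target C, `strand`).
#' @export
count_motif_targets <- function(genome, motif, target_offset = NULL) {
  g <- genome_chars(genome)
  motif <- toupper(motif)
  if (grepl("[^ACGTRYSWKMBDHVN]", motif)) stop("invalid IUPAC motif: ", motif)
  if (is.null(target_offset)) target_offset <- default_target_offset(motif)
  L <- nchar(motif)
  if (target_offset < 0L || target_offset >= L) {
    stop("target_offset outside motif")
  }
  if (!"C" %in% iupac_bases(substr(motif, target_offset + 1L, target_offset + 1L))) {
    stop("motif position ", target_offset, " cannot be a C (",
         substr(motif, target_offset + 1L, target_offset + 1L), ")")
  }
  rc <- revcomp(motif)
  res <- vector("list", length(g))
  for (i in seq_along(g)) {
    ctg <- names(g)[i]
    st_p <- .match_motif_starts(g[[ctg]], motif)
    st_m <- .match_motif_starts(g[[ctg]], rc)
    res[[i]] <- data.frame(
      contig = rep(ctg, length(st_p) + length(st_m)),
      pos = c(st_p + target_offset, st_m + (L - 1L - target_offset)),
      strand = rep(c("+", "-"), c(length(st_p), length(st_m))),
      stringsAsFactors = FALSE
    )
  }
  positions <- do.call(rbind, res)
  positions <- positions[order(positions$contig, positions$pos, positions$strand), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  list(n_sites = nrow(positions), positions = positions)
}

#' Analytical resolution of a motif-based assay
#'
#' The mean genomic spacing of a motif's target cytosines: genome size
#' divided by the number of target sites, rounded to the nearest integer
#' (halves away from zero).
#'
#' @param genome_size genome length in bp.
#' @param n_sites number of target sites (`> 0`).
#' @return resolution in bp (integer-valued numeric).
#' @export
analytical_resolution <- function(genome_size, n_sites) {
  if (any(n_sites <= 0)) stop("n_sites must be positive")
  round_half_away(genome_size / n_sites)
}

#' Read-coverage summary over a motif's target sites
#'
#' @param records cytosine records restricted to the motif's target sites.
#' @param threshold minimum read depth for a site to count as covered.
#' @param n_sites total number of target sites in the genome (denominator);
#'   defaults to `nrow(records)`.
#' @return list with `n_covered`, `covered_fraction` (percent) and
#'   `degenerate` (`TRUE` when `n_sites` is 0, fraction reported as 0).
#' @export
coverage_summary <- function(records, threshold = 10L, n_sites = nrow(records)) {
  stopifnot(threshold >= 0L)
  n_covered <- sum(records$meth + records$unmeth >= threshold)
  if (n_sites == 0L) {
    return(list(n_covered = 0L, covered_fraction = 0, degenerate = TRUE))
  }
  list(n_covered = n_covered,
       covered_fraction = 100 * n_covered / n_sites,
       degenerate = FALSE)
}

#' Motif census table (site counts, resolution, coverage)
#'
#' One row per motif: genome-wide target-site count, analytical resolution,
#' and the number/fraction of target sites covered by at least `threshold`
#' reads in the supplied methylation report.
#'
#' @param genome genome as from [read_genome()].
#' @param records a `cytosine_report` (the coverage source).
#' @param motifs character vector of IUPAC motifs.
#' @param target_offsets optional integer vector (0-based target C index per
#'   motif); defaults to the first literal `C` of each motif.
#' @param threshold coverage threshold in reads.
#' @return `data.frame` with columns `motif`, `target_offset`,
#'   `genome_size`, `n_sites`, `resolution`, `n_covered`, `covered_fraction`.
#' @export
census_table <- function(genome, records, motifs, target_offsets = NULL,
                         threshold = 10L) {
  g <- genome_chars(genome)
  genome_size <- sum(nchar(g))
  if (is.null(target_offsets)) {
    target_offsets <- vapply(motifs, default_target_offset, integer(1))
  }
  stopifnot(length(target_offsets) == length(motifs))
  rec_key <- paste(records$contig, records$pos, records$strand)
  rows <- lapply(seq_along(motifs), function(i) {
    tg <- count_motif_targets(genome, motifs[i], target_offsets[i])
    tg_key <- paste(tg$positions$contig, tg$positions$pos, tg$positions$strand)
    cov <- coverage_summary(records[rec_key %in% tg_key, , drop = FALSE],
                            threshold = threshold, n_sites = tg$n_sites)
    data.frame(
      motif = motifs[i], target_offset = as.integer(target_offsets[i]),
      genome_size = genome_size, n_sites = tg$n_sites,
      resolution = if (tg$n_sites > 0) analytical_resolution(genome_size, tg$n_sites) else NA,
      n_covered = cov$n_covered, covered_fraction = cov$covered_fraction,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res <- res %||% data.frame(motif = character(0))
  rownames(res) <- NULL
  res
}

#' Define a methylation-sensitive restriction enzyme
#'
#' @param name enzyme name.
#' @param site recognition site (IUPAC).
#' @param cut_offset cut position in bp from the site start (0-based: a cut
#'   offset of 2 cuts between site positions 1 and 2).
#' @param blocking data.frame of (`offset`, `strand`) pairs: site positions
#'   whose 5-methylcytosine blocks cleavage. Offsets are 0-based within the
#'   site; minus-strand entries name the cytosine paired to the plus-strand
#'   base at that offset.
#' @return object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, site, cut_offset, blocking) {
  site <- toupper(site)
  stopifnot(is.data.frame(blocking), all(c("offset", "strand") %in% names(blocking)))
  if (cut_offset < 0L || cut_offset > nchar(site)) stop("cut_offset outside site")
  for (i in seq_len(nrow(blocking))) {
    off <- blocking$offset[i]
    if (off < 0L || off >= nchar(site)) stop("blocking offset outside site")
    b <- substr(site, off + 1L, off + 1L)
    ok <- if (blocking$strand[i] == "+") "C" %in% iupac_bases(b)
          else "G" %in% iupac_bases(b)
    if (!ok) stop("blocking position ", off, blocking$strand[i],
                  " of ", name, " is not a cytosine")
  }
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset),
                 blocking = blocking),
            class = "restriction_enzyme")
}

#' Built-in methylation-sensitive enzymes
#'
#' `HaeIII` (GG^CC) is blocked by 5mC of the first C of its CC — site
#' offset 2 on the plus strand or the mirrored position (offset 1) on the
#' minus strand. `HpaII` (C^CGG) is blocked by 5mC at either of its
#' plus-strand cytosines (offsets 0 and 1) or their minus-strand mirrors.
#'
#' @param name `"HaeIII"` or `"HpaII"`.
#' @return a `restriction_enzyme`.
#' @export
builtin_enzyme <- function(name) {
  switch(name,
    HaeIII = restriction_enzyme("HaeIII", "GGCC", 2L,
      data.frame(offset = c(2L, 1L), strand = c("+", "-"))),
    HpaII = restriction_enzyme("HpaII", "CCGG", 1L,
      data.frame(offset = c(0L, 1L, 3L, 2L), strand = c("+", "+", "-", "-"))),
    stop("unknown enzyme: ", name)
  )
}

#' In-silico methylation-sensitive restriction digest
#'
#' Scans each contig (plus strand; both orientations for non-palindromic
#' sites) for the enzyme's recognition site and cuts every occurrence at
#' which no blocking position carries a methylated cytosine. A cytosine
#' counts as methylated when its level in `records` is at least
#' `level_threshold`; cytosines absent from `records` are treated as
#' unmethylated. Contigs are linear; fragments tile each contig exactly.
#'
#' @param genome genome as from [read_genome()].
#' @param records a `cytosine_report` giving methylation state (may have
#'   zero rows for a fully unmethylated digest).
#' @param enzyme a `restriction_enzyme` (see [builtin_enzyme()]).
#' @param level_threshold methylation level at or above which a cytosine
#'   blocks cleavage.
#' @return list with `cuts` (named list of 0-based cut positions per
#'   contig) and `fragments` (data.frame `contig`, `start`, `end`,
#'   `length`; 0-based half-open).
#' @export
digest_in_silico <- function(genome, records, enzyme, level_threshold = 0.5) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  g <- genome_chars(genome)
  lvl <- meth_level(records$meth, records$unmeth)
  meth_key <- paste(records$contig, records$pos, records$strand)[
    !is.na(lvl) & lvl >= level_threshold]
  L <- nchar(enzyme$site)
  rc_site <- revcomp(enzyme$site)
  cuts <- vector("list", length(g))
  names(cuts) <- names(g)
  frags <- vector("list", length(g))
  for (i in seq_along(g)) {
    ctg <- names(g)[i]
    n <- nchar(g[[ctg]])
    occ <- data.frame(start = .match_motif_starts(g[[ctg]], enzyme$site),
                      plus = TRUE)
    if (rc_site != enzyme$site) {
      occ <- rbind(occ, data.frame(start = .match_motif_starts(g[[ctg]], rc_site),
                                   plus = FALSE))
    }
    cut_pos <- integer(0)
    if (nrow(occ)) {
      blocked <- vapply(seq_len(nrow(occ)), function(r) {
        s <- occ$start[r]
        if (occ$plus[r]) {
          off <- enzyme$blocking$offset
          std <- enzyme$blocking$strand
        } else {
          off <- L - 1L - enzyme$blocking$offset
          std <- ifelse(enzyme$blocking$strand == "+", "-", "+")
        }
        any(paste(ctg, s + off, std) %in% meth_key)
      }, logical(1))
      co <- ifelse(occ$plus, enzyme$cut_offset, L - enzyme$cut_offset)
      cut_pos <- sort(unique((occ$start[!blocked] - 1L) + co[!blocked]))
      cut_pos <- cut_pos[cut_pos > 0L & cut_pos < n]
    }
    cuts[[i]] <- cut_pos
    bounds <- c(0L, cut_pos, n)
    frags[[i]] <- data.frame(contig = ctg, start = bounds[-length(bounds)],
                             end = bounds[-1], stringsAsFactors = FALSE)
  }
  fragments <- do.call(rbind, frags)
  fragments$length <- fragments$end - fragments$start
  rownames(fragments) <- NULL
  list(cuts = cuts, fragments = fragments)
}
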