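# NOMe-Seq analytics: channel separation, binned tracks, anchor-centred
# aggregation, nucleosome periodicity, and a simple accessible-region caller.

# strand-local previous/next base for each record
.record_neighbours <- function(records, genome) {
  g <- genome_chars(genome)
  len <- nchar(g)[records$contig]
  plus <- records$strand == "+"
  nxt <- prv <- rep("N", nrow(records))
  at <- function(p) {
    out <- rep("N", length(p))
    ok <- p >= 1L & p <= len
    out[ok] <- substring(g[records$contig[ok]], p[ok], p[ok])
    out
  }
  nxt[plus] <- at(records$pos + 1L)[plus]
  prv[plus] <- at(records$pos - 1L)[plus]
  comp <- .COMPLEMENT
  nxt[!plus] <- unname(comp[at(records$pos - 1L)[!plus]])
  prv[!plus] <- unname(comp[at(records$pos + 1L)[!plus]])
  data.frame(prev = prv, nxt = nxt, stringsAsFactors = FALSE)
}

#' Channel specification for NOMe-Seq separation
#'
#' In `GCMT` mode (GC-methylating probe) intrinsic CG methylation is read
#' from `HCG` sites and induced methylation from `GCH` sites, while the
#' ambiguous `GCG` trinucleotide — where intrinsic and induced methylation
#' cannot be told apart — is excluded. In `CCMT` mode (CC-methylating probe)
#' the recognition sequence does not overlap CG at all, so intrinsic = all
#' CG-context cytosines and induced = all CC-context cytosines (first C of
#' the CC), with nothing excluded.
#'
#' @param mode `"GCMT"` or `"CCMT"`.
#' @return list with `mode`, `intrinsic`, `induced`, `excluded` labels.
#' @export
channel_spec <- function(mode = c("GCMT", "CCMT")) {
  mode <- match.arg(mode)
  if (mode == "GCMT") {
    list(mode = mode, intrinsic = "HCG", induced = "GCH", excluded = "GCG")
  } else {
    list(mode = mode, intrinsic = "CG", induced = "CC", excluded = character(0))
  }
}

#' Split cytosine records into intrinsic and induced methylation channels
#'
#' Assigns every record to exactly one of four classes — `intrinsic`,
#' `induced`, `excluded`, `other` — according to its sequence context in
#' the genome (see [channel_spec()]). Records whose deciding neighbour is
#' undefined (contig edge, `N`) fall into `other`.
#'
#' @param records a `cytosine_report`.
#' @param genome genome as from [read_genome()].
#' @param mode `"GCMT"` or `"CCMT"` (or a [channel_spec()] list).
#' @return list of four `cytosine_report`s: `intrinsic`, `induced`,
#'   `excluded`, `other`, plus the `spec` used.
#' @export
split_channels <- function(records, genome, mode = "GCMT") {
  spec <- if (is.list(mode)) mode else channel_spec(mode)
  nb <- .record_neighbours(records, genome)
  h <- c("A", "C", "T")
  cls <- rep("other", nrow(records))
  if (spec$mode == "GCMT") {
    cg <- nb$nxt == "G"
    cls[cg & nb$prev %in% h] <- "intrinsic"      # HCG
    cls[cg & nb$prev == "G"] <- "excluded"       # GCG
    cls[nb$prev == "G" & nb$nxt %in% h] <- "induced"  # GCH
  } else if (spec$mode == "CCMT") {
    cls[nb$nxt == "G"] <- "intrinsic"            # CG
    cls[nb$nxt == "C"] <- "induced"              # CC (first C)
  } else {
    stop("unknown channel mode: ", spec$mode)
  }
  out <- lapply(c(intrinsic = "intrinsic", induced = "induced",
                  excluded = "excluded", other = "other"),
                function(x) {
                  r <- records[cls == x, , drop = FALSE]
                  rownames(r) <- NULL
                  r
                })
  c(out, list(spec = spec))
}

#' Bin per-cytosine methylation into a fixed-width track
#'
#' Levels are coverage-weighted within each bin: the pooled methylated
#' count over the pooled total count, not the mean of per-site levels.
#' Bins with no read support are omitted.
#'
#' @param records a `cytosine_report`.
#' @param bin_size bin width in bp (default 10).
#' @return a `binned_track` with pooled `level` and `depth` per bin.
#' @export
bin_levels <- function(records, bin_size = 10L) {
  stopifnot(bin_size >= 1L)
  if (nrow(records) == 0L) {
    return(binned_track(character(0), integer(0), integer(0), numeric(0)))
  }
  start <- ((records$pos - 1L) %/% bin_size) * bin_size
  key <- paste(records$contig, start, sep = "\r")
  meth <- rowsum(records$meth, key)
  tot <- rowsum(records$meth + records$unmeth, key)
  keep <- tot[, 1] > 0
  ks <- strsplit(rownames(meth)[keep], "\r", fixed = TRUE)
  binned_track(
    contig = vapply(ks, `[`, "", 1L),
    start = as.integer(vapply(ks, `[`, "", 2L)),
    end = as.integer(vapply(ks, `[`, "", 2L)) + bin_size,
    level = meth[keep, 1] / tot[keep, 1],
    depth = tot[keep, 1]
  )
}

#' Aggregate methylation levels around anchors
#'
#' Places every covered cytosine within `flank` bp of each anchor at its
#' strand-oriented offset (minus-strand anchors flip sign so that negative
#' offsets are always upstream of the anchor), then averages per-site
#' levels per offset across all anchors — an unweighted mean of site
#' levels, so deep sites do not dominate. Offsets with no contributing
#' sites are absent from the result.
#'
#' @param records a `cytosine_report`.
#' @param anchors an `anchor_set` (0-based anchor positions).
#' @param flank half-width of the profile in bp.
#' @return `data.frame` of class `aggregation_profile` with `offset`,
#'   `mean_level`, `n_sites`.
#' @export
aggregate_profile <- function(records, anchors, flank = 1000L) {
  stopifnot(flank >= 1L)
  if (nrow(anchors) == 0L) stop("empty anchor set")
  width <- 2L * flank + 1L
  sums <- counts <- numeric(width)
  tot <- records$meth + records$unmeth
  covered <- tot > 0L
  for (ctg in unique(anchors$contig)) {
    ri <- which(records$contig == ctg & covered)
    if (!length(ri)) next
    pos0 <- records$pos[ri] - 1L
    o <- order(pos0)
    ri <- ri[o]; pos0 <- pos0[o]
    lev <- records$meth[ri] / tot[ri]
    ai <- which(anchors$contig == ctg)
    for (a in ai) {
      ap <- anchors$pos[a]
      lo <- findInterval(ap - flank - 1L, pos0) + 1L
      hi <- findInterval(ap + flank, pos0)
      if (hi < lo) next
      off <- pos0[lo:hi] - ap
      if (anchors$strand[a] == "-") off <- -off
      idx <- off + flank + 1L
      counts <- counts + tabulate(idx, nbins = width)  # one site, one vote
      rs <- rowsum(lev[lo:hi], idx)
      sums[as.integer(rownames(rs))] <- sums[as.integer(rownames(rs))] + rs[, 1]
    }
  }
  keep <- counts > 0
  prof <- data.frame(offset = seq.int(-flank, flank)[keep],
                     mean_level = sums[keep] / counts[keep],
                     n_sites = as.integer(counts[keep]))
  class(prof) <- c("aggregation_profile", "data.frame")
  prof
}

#' Estimate nucleosome periodicity from an aggregation profile
#'
#' Linearly interpolates missing offsets, mean-subtracts, and returns the
#' lag in `[min_period, max_period]` that maximises the autocorrelation.
#' The estimate is flagged low-confidence when the autocorrelation at the
#' chosen lag falls below the prominence floor (0.1), as happens for
#' structureless profiles.
#'
#' @param profile an `aggregation_profile`.
#' @param min_period,max_period search range in bp.
#' @param prominence_floor autocorrelation value below which the estimate
#'   is flagged unconfident.
#' @return list with `period` (bp), `acf_peak`, `confident`, and the full
#'   `acf` vector over the searched lags.
#' @export
estimate_periodicity <- function(profile, min_period = 120L, max_period = 220L,
                                 prominence_floor = 0.1) {
  stopifnot(min_period >= 1L, max_period > min_period)
  grid <- seq.int(min(profile$offset), max(profile$offset))
  if (length(grid) < 3L * max_period) {
    stop("profile span (", length(grid), " bp) shorter than 3 * max_period")
  }
  y <- stats::approx(profile$offset, profile$mean_level, xout = grid,
                     rule = 2)$y
  ac <- stats::acf(y, lag.max = max_period, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq.int(min_period, max_period)
  vals <- ac[lags + 1L]
  best <- which.max(vals)
  list(period = lags[best], acf_peak = vals[best],
       confident = vals[best] >= prominence_floor,
       acf = stats::setNames(vals, lags))
}

#' Call accessible regions from an induced-methylation track
#'
#' A deliberately simple threshold segmenter (not a peak caller): maximal
#' runs of bins with level at or above `level_threshold`, merged across
#' gaps up to `merge_gap` bp, kept when at least `min_len` bp long.
#'
#' @param track a `binned_track` of induced methylation.
#' @param level_threshold minimum bin level.
#' @param min_len minimum region length in bp.
#' @param merge_gap maximum gap bridged between qualifying bins, bp.
#' @return `data.frame` with `contig`, `start`, `end`, `mean_level`
#'   (0-based half-open), class `accessible_regions`.
#' @export
call_accessible_regions <- function(track, level_threshold = 0.5,
                                    min_len = 100L, merge_gap = 20L) {
  stopifnot(level_threshold > 0, min_len > 0)
  sel <- track[track$level >= level_threshold, , drop = FALSE]
  out <- list()
  for (ctg in unique(sel$contig)) {
    tr <- sel[sel$contig == ctg, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (!nrow(tr)) next
    new_run <- c(TRUE, tr$start[-1] - tr$end[-nrow(tr)] > merge_gap)
    run <- cumsum(new_run)
    for (r in unique(run)) {
      b <- tr[run == r, , drop = FALSE]
      st <- min(b$start); en <- max(b$end)
      if (en - st >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start = st, end = en,
          mean_level = mean(b$level), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               mean_level = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("accessible_regions", "data.frame")
  res
}

#' Compare two binned methylation tracks
#'
#' Inner join on bin coordinates; Pearson and Spearman correlations are
#' computed over shared bins whose depth reaches `depth_floor` in both
#' tracks (bins with unknown depth are kept).
#'
#' @param a,b `binned_track`s over the same genome.
#' @param depth_floor minimum pooled depth per bin in both tracks.
#' @return list with `pearson`, `spearman`, `n_bins`, and the joined
#'   `bins` data.frame (`level_a`, `level_b`).
#' @export
compare_tracks <- function(a, b, depth_floor = 5L) {
  ka <- paste(a$contig, a$start, a$end)
  kb <- paste(b$contig, b$start, b$end)
  i <- match(ka, kb)
  sel <- !is.na(i)
  da <- a$depth[sel]
  db <- b$depth[i[sel]]
  ok <- (is.na(da) | da >= depth_floor) & (is.na(db) | db >= depth_floor)
  joined <- data.frame(contig = a$contig[sel][ok],
                       start = a$start[sel][ok], end = a$end[sel][ok],
                       level_a = a$level[sel][ok],
                       level_b = b$level[i[sel]][ok])
  if (nrow(joined) == 0L) stop("tracks share no bins at the depth floor")
  list(pearson = stats::cor(joined$level_a, joined$level_b),
       spearman = stats::cor(joined$level_a, joined$level_b, method = "spearman"),
       n_bins = nrow(joined), bins = joined)
}
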