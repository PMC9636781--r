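# Synthetic genomes and methylomes emulating the statistical structure the
# analyses assume: planted MTase recognition motifs at a given efficiency,
# binomial read sampling at Poisson coverage over a bisulfite
# non-conversion background, nucleosome-structured accessibility with
# promoter NDRs, and an intrinsic CG landscape of highly- and
# partially-methylated domains. All generators are pure functions of their
# specs and seeds.

#' Simulate a random genome
#'
#' Generates contigs either i.i.d. from `base_freqs` or from a first-order
#' Markov chain with the given 4x4 `transition` matrix (rows = current
#' base A/C/G/T, columns = next base). Deterministic given `seed`.
#'
#' @param length total length in bp (split evenly across contigs).
#' @param n_contigs number of contigs.
#' @param base_freqs named frequencies for A/C/G/T (must sum to 1).
#' @param transition optional 4x4 row-stochastic matrix for a first-order
#'   dinucleotide model; overrides `base_freqs` beyond the first base.
#' @param seed RNG seed.
#' @param contig_prefix contig name prefix.
#' @return a [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(length, n_contigs = 1L,
                            base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            transition = NULL, seed = 1L,
                            contig_prefix = "contig") {
  stopifnot(length >= 0, n_contigs >= 1L)
  base_freqs <- base_freqs[BASES]
  if (anyNA(base_freqs) || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-8) {
    stop("base_freqs must be named A/C/G/T frequencies summing to 1")
  }
  if (!is.null(transition)) {
    if (!all(dim(transition) == c(4L, 4L)) ||
        any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0)) {
      stop("transition must be a 4x4 row-stochastic matrix")
    }
  }
  sizes <- rep(length %/% n_contigs, n_contigs)
  if (n_contigs >= 1L) sizes[n_contigs] <- sizes[n_contigs] + length %% n_contigs
  with_seed(seed, {
    seqs <- vapply(sizes, function(n) {
      if (n == 0L) return("")
      if (is.null(transition)) {
        paste(sample(BASES, n, replace = TRUE, prob = base_freqs),
              collapse = "")
      } else {
        cum <- t(apply(transition, 1L, cumsum))
        u <- stats::runif(n)
        b <- integer(n)
        b[1] <- sample.int(4L, 1L, prob = base_freqs)
        if (n > 1L) for (i in 2:n) {
          b[i] <- findInterval(u[i], cum[b[i - 1L], ]) + 1L
        }
        paste(BASES[b], collapse = "")
      }
    }, character(1))
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- sprintf("%s_%d", contig_prefix, seq_len(n_contigs))
    g
  })
}

#' MTase specification for simulation
#'
#' @param motif IUPAC recognition sequence.
#' @param target_offset 0-based index of the methylated C (defaults to the
#'   first literal `C`).
#' @param efficiency mean methylation level deposited at target sites.
#' @param concentration Beta concentration: site levels are drawn from
#'   `Beta(efficiency * c, (1 - efficiency) * c)`; `Inf` gives the constant
#'   `efficiency`.
#' @param overrides optional named numeric vector mapping a trinucleotide
#'   context (e.g. `CCC`) to a replacement efficiency mean, emulating
#'   context-dependent weakness of an enzyme.
#' @return list of class `mtase_spec`.
#' @export
mtase_spec <- function(motif, target_offset = NULL, efficiency = 0.85,
                       concentration = 100, overrides = NULL) {
  motif <- toupper(motif)
  if (is.null(target_offset)) target_offset <- default_target_offset(motif)
  stopifnot(efficiency >= 0, efficiency <= 1, concentration > 0)
  structure(list(motif = motif, target_offset = as.integer(target_offset),
                 efficiency = efficiency, concentration = concentration,
                 overrides = overrides),
            class = "mtase_spec")
}

#' Intrinsic CG-methylation landscape specification
#'
#' A two-state domain model over CG targets: the genome alternates between
#' highly methylated regions and partially methylated domains with
#' geometrically distributed lengths; within a domain, site levels are
#' drawn from a Beta around the domain mean.
#'
#' @param high_mean mean level in highly methylated regions.
#' @param partial_mean mean level in partially methylated domains.
#' @param mean_domain_length mean domain length in bp.
#' @param p_high stationary probability of the highly methylated state.
#' @param concentration Beta concentration of site levels around the
#'   domain mean.
#' @param seed optional landscape seed. When set, the drawn landscape is a
#'   property of the spec itself, shared across simulation runs — e.g. a
#'   treated and an untreated library of the same biological sample. When
#'   `NULL`, the landscape derives from the run seed.
#' @return list of class `intrinsic_spec`.
#' @export
intrinsic_spec <- function(high_mean = 0.85, partial_mean = 0.4,
                           mean_domain_length = 30000, p_high = 0.5,
                           concentration = 50, seed = NULL) {
  stopifnot(high_mean >= 0, high_mean <= 1, partial_mean >= 0,
            partial_mean <= 1, mean_domain_length >= 1)
  structure(list(high_mean = high_mean, partial_mean = partial_mean,
                 mean_domain_length = mean_domain_length, p_high = p_high,
                 concentration = concentration, seed = seed),
            class = "intrinsic_spec")
}

#' Read-coverage specification
#'
#' @param lambda mean read depth per cytosine (i.i.d. Poisson).
#' @param background apparent methylation level of unmethylated cytosines
#'   (bisulfite non-conversion and other background).
#' @return list of class `coverage_spec`.
#' @export
coverage_spec <- function(lambda = 20, background = 0.002) {
  stopifnot(lambda > 0, background >= 0, background < 1)
  structure(list(lambda = lambda, background = background),
            class = "coverage_spec")
}

#' Chromatin specification for NOMe simulation
#'
#' Promoter anchors carry a nucleosome-depleted region at `ndr` (bp
#' relative to the anchor, strand-oriented; default `[-250, -100]`, the
#' promoter-proximal window where induced methylation concentrates).
#' Nucleosomes of `footprint` bp are tiled at `period` bp spacing outward
#' from the NDR edges; accessibility is 1 in NDRs and linkers and
#' `1 - protection` under footprints.
#'
#' @param anchors an `anchor_set`.
#' @param ndr length-2 numeric, NDR interval relative to the anchor.
#' @param footprint nucleosome footprint, bp.
#' @param period nucleosome repeat length, bp (>= footprint).
#' @param protection fraction of MTase activity blocked under a footprint.
#' @param jitter_sd SD in bp of Gaussian jitter on each nucleosome start
#'   (0 = deterministic phasing).
#' @return list of class `chromatin_spec`.
#' @export
chromatin_spec <- function(anchors, ndr = c(-250, -100), footprint = 147L,
                           period = 165L, protection = 0.95, jitter_sd = 0) {
  stopifnot(inherits(anchors, "anchor_set"), length(ndr) == 2L,
            ndr[1] < ndr[2], footprint <= period,
            protection >= 0, protection <= 1)
  structure(list(anchors = anchors, ndr = as.integer(ndr),
                 footprint = as.integer(footprint), period = as.integer(period),
                 protection = protection, jitter_sd = jitter_sd),
            class = "chromatin_spec")
}

# every cytosine on both strands with its strand-local trinucleotide context
.enumerate_cytosines <- function(genome) {
  g <- genome_chars(genome)
  out <- vector("list", 2L * length(g))
  k <- 0L
  for (ctg in names(g)) {
    s <- g[[ctg]]
    n <- nchar(s)
    ch <- strsplit(s, "")[[1]]
    padded <- paste0(s, "NN")
    for (std in c("+", "-")) {
      pos <- if (std == "+") which(ch == "C") else which(ch == "G")
      if (!length(pos)) next
      ctx <- if (std == "+") {
        substring(padded, pos, pos + 2L)
      } else {
        lo <- pmax(pos - 2L, 1L)
        raw <- substring(s, lo, pos)
        short <- nchar(raw) < 3L
        raw[short] <- paste0(strrep("N", 3L - nchar(raw[short])), raw[short])
        revcomp(raw)
      }
      k <- k + 1L
      out[[k]] <- data.frame(contig = ctg, pos = pos, strand = std,
                             context = ctx, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$contig, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# draw per-target-site levels for one MTase spec (runs inside a seeded stream)
.mtase_draw <- function(spec, contexts) {
  mu <- rep(spec$efficiency, length(contexts))
  if (!is.null(spec$overrides)) {
    for (ctx in names(spec$overrides)) mu[contexts == ctx] <- spec$overrides[[ctx]]
  }
  if (is.infinite(spec$concentration)) return(mu)
  c0 <- spec$concentration
  lv <- stats::rbeta(length(mu), mu * c0, (1 - mu) * c0)
  # rbeta returns NaN for degenerate shape 0; map back to the point mass
  lv[mu == 0] <- 0
  lv[mu == 1] <- 1
  lv
}

# intrinsic CG landscape: per-cytosine level (NA off the CG channel)
.intrinsic_levels <- function(genome, cyto, spec, seed) {
  g <- genome_chars(genome)
  lv <- rep(NA_real_, nrow(cyto))
  is_cg <- substr(cyto$context, 2L, 2L) == "G"
  with_seed(seed, {
    for (ctg in names(g)) {
      n <- nchar(g[[ctg]])
      if (n == 0L) next
      # alternate H/P domains with geometric lengths along the contig
      state <- stats::runif(1) < spec$p_high
      bp <- 0L
      means <- numeric(n)
      while (bp < n) {
        len <- 1L + stats::rgeom(1L, 1 / spec$mean_domain_length)
        hi <- min(bp + len, n)
        means[(bp + 1L):hi] <- if (state) spec$high_mean else spec$partial_mean
        state <- !state
        bp <- hi
      }
      sel <- which(cyto$contig == ctg & is_cg)
      if (!length(sel)) next
      mu <- means[cyto$pos[sel]]
      c0 <- spec$concentration
      draw <- stats::rbeta(length(mu), mu * c0, (1 - mu) * c0)
      draw[mu == 0] <- 0
      draw[mu == 1] <- 1
      lv[sel] <- draw
    }
  })
  lv
}

# Poisson depth + binomial methylated counts for given true levels
.sample_counts <- function(true_level, coverage, seed) {
  with_seed(seed, {
    depth <- stats::rpois(length(true_level), coverage$lambda)
    meth <- stats::rbinom(length(true_level), depth, true_level)
    data.frame(depth = depth, meth = meth)
  })
}

#' Simulate a whole-genome bisulfite methylome
#'
#' Per cytosine (both strands), the true methylation level is the maximum of
#' the background (non-conversion) rate, a Beta draw around each MTase's
#' efficiency at its target sites, and — when an intrinsic landscape is
#' given — the domain-model level at CG targets. Sources combine by `max`
#' because they are redundant causes of the same 5mC mark, and a level is a
#' probability. Read depth is i.i.d. Poisson and observed methylated counts
#' are Binomial(depth, level). Deterministic given `seed` (independent
#' sub-streams per component, so the intrinsic landscape of a genome is the
#' same with or without MTase treatment).
#'
#' @param genome genome as from [read_genome()] or [simulate_genome()].
#' @param mtases a `mtase_spec` or list of them (may be empty).
#' @param intrinsic optional `intrinsic_spec`.
#' @param coverage a `coverage_spec`.
#' @param seed RNG seed.
#' @return list with `report` (a `cytosine_report`) and `truth`
#'   (data.frame of per-cytosine `true_level` and `is_target`).
#' @export
simulate_methylome <- function(genome, mtases = list(),
                               intrinsic = NULL,
                               coverage = coverage_spec(), seed = 1L) {
  if (inherits(mtases, "mtase_spec")) mtases <- list(mtases)
  cyto <- .enumerate_cytosines(genome)
  true <- rep(coverage$background, nrow(cyto))
  is_target <- rep(FALSE, nrow(cyto))
  key <- paste(cyto$contig, cyto$pos, cyto$strand)
  for (i in seq_along(mtases)) {
    sp <- mtases[[i]]
    tg <- count_motif_targets(genome, sp$motif, sp$target_offset)
    sel <- match(paste(tg$positions$contig, tg$positions$pos,
                       tg$positions$strand), key)
    sel <- sel[!is.na(sel)]
    if (!length(sel)) next
    is_target[sel] <- TRUE
    lv <- with_seed(sub_seed(seed, 100L + i),
                    .mtase_draw(sp, cyto$context[sel]))
    true[sel] <- pmax(true[sel], lv)
  }
  if (!is.null(intrinsic)) {
    ilv <- .intrinsic_levels(genome, cyto, intrinsic,
                             intrinsic$seed %||% sub_seed(seed, 1L))
    sel <- !is.na(ilv)
    true[sel] <- pmax(true[sel], ilv[sel])
  }
  cnt <- .sample_counts(true, coverage, sub_seed(seed, 2L))
  report <- cytosine_report(cyto$contig, cyto$pos, cyto$strand,
                            cnt$meth, cnt$depth - cnt$meth, cyto$context)
  truth <- cbind(cyto, true_level = true, is_target = is_target)
  list(report = report, truth = truth)
}

# per-bp accessibility vectors, one per contig
.accessibility <- function(genome, chromatin, seed) {
  g <- genome_chars(genome)
  anc <- chromatin$anchors
  acc <- lapply(nchar(g), function(n) rep(1, n))
  names(acc) <- names(g)
  foot <- chromatin$footprint
  per <- chromatin$period
  prot <- chromatin$protection
  with_seed(seed, {
    for (ctg in names(g)) {
      n <- nchar(g[[ctg]])
      ai <- which(anc$contig == ctg)
      if (any(anc$pos[ai] < 0L | anc$pos[ai] >= n)) {
        stop("anchor outside contig ", ctg)
      }
      occupied <- rep(FALSE, n)
      place <- function(from, to, leftward = FALSE) {
        # tile footprints at `per` spacing inside [from, to) (0-based)
        if (to - from < foot) return()
        starts <- seq.int(from, to - foot, by = per)
        if (leftward) starts <- starts + ((to - from - foot) %% per)
        if (chromatin$jitter_sd > 0) {
          starts <- starts + as.integer(round(stats::rnorm(length(starts), 0,
                                                           chromatin$jitter_sd)))
          starts <- pmax(pmin(starts, to - foot), from)
        }
        for (s in starts) occupied[(s + 1L):(s + foot)] <<- TRUE
      }
      if (!length(ai)) {
        # no anchors: an unbroken nucleosome array phased from the
        # contig start
        place(0L, n)
        acc[[ctg]][occupied] <- 1 - prot
        next
      }
      # strand-oriented NDR intervals (0-based half-open)
      st <- ifelse(anc$strand[ai] == "+",
                   anc$pos[ai] + chromatin$ndr[1],
                   anc$pos[ai] - chromatin$ndr[2])
      en <- ifelse(anc$strand[ai] == "+",
                   anc$pos[ai] + chromatin$ndr[2] + 1L,
                   anc$pos[ai] - chromatin$ndr[1] + 1L)
      st <- pmax(st, 0L); en <- pmin(en, n)
      o <- order(st)
      st <- st[o]; en <- en[o]
      # leftmost segment is tiled leftward from the first NDR's left edge
      place(0L, st[1], leftward = TRUE)
      for (i in seq_along(st)) {
        seg_end <- if (i < length(st)) st[i + 1L] else n
        place(en[i], seg_end)
      }
      # NDRs override any footprint that strays into them
      for (i in seq_along(st)) if (en[i] > st[i]) {
        occupied[(st[i] + 1L):en[i]] <- FALSE
      }
      acc[[ctg]][occupied] <- 1 - prot
    }
  })
  acc
}

#' Simulate a NOMe-Seq experiment
#'
#' Combines an MTase probe with a nucleosome-structured accessibility
#' landscape: the induced true level at each target cytosine is the MTase
#' efficiency draw scaled by the local accessibility (1 in NDRs and
#' linkers, `1 - protection` under nucleosome footprints tiled at the spec
#' period from each NDR edge), floored at the background rate. The
#' intrinsic CG channel, when given, is unaffected by accessibility.
#'
#' @inheritParams simulate_methylome
#' @param mtase a single `mtase_spec` (the accessibility probe).
#' @param chromatin a `chromatin_spec`.
#' @return list with `report`, `truth` (including `accessibility` per
#'   cytosine), and `accessibility_track` (a `binned_track` of the per-bp
#'   truth, run-length compressed).
#' @export
simulate_nome <- function(genome, mtase, chromatin, intrinsic = NULL,
                          coverage = coverage_spec(), seed = 1L) {
  stopifnot(inherits(mtase, "mtase_spec"), inherits(chromatin, "chromatin_spec"))
  cyto <- .enumerate_cytosines(genome)
  acc <- .accessibility(genome, chromatin, sub_seed(seed, 3L))
  acc_at <- numeric(nrow(cyto))
  for (ctg in names(acc)) {
    sel <- cyto$contig == ctg
    acc_at[sel] <- acc[[ctg]][cyto$pos[sel]]
  }
  true <- rep(coverage$background, nrow(cyto))
  is_target <- rep(FALSE, nrow(cyto))
  key <- paste(cyto$contig, cyto$pos, cyto$strand)
  tg <- count_motif_targets(genome, mtase$motif, mtase$target_offset)
  sel <- match(paste(tg$positions$contig, tg$positions$pos,
                     tg$positions$strand), key)
  sel <- sel[!is.na(sel)]
  if (length(sel)) {
    is_target[sel] <- TRUE
    lv <- with_seed(sub_seed(seed, 101L), .mtase_draw(mtase, cyto$context[sel]))
    true[sel] <- pmax(true[sel], lv * acc_at[sel])
  }
  if (!is.null(intrinsic)) {
    ilv <- .intrinsic_levels(genome, cyto, intrinsic,
                             intrinsic$seed %||% sub_seed(seed, 1L))
    isel <- !is.na(ilv)
    true[isel] <- pmax(true[isel], ilv[isel])
  }
  cnt <- .sample_counts(true, coverage, sub_seed(seed, 2L))
  report <- cytosine_report(cyto$contig, cyto$pos, cyto$strand,
                            cnt$meth, cnt$depth - cnt$meth, cyto$context)
  truth <- cbind(cyto, true_level = true, is_target = is_target,
                 accessibility = acc_at)
  # run-length-compressed accessibility truth track
  tracks <- lapply(names(acc), function(ctg) {
    r <- rle(acc[[ctg]])
    en <- cumsum(r$lengths)
    data.frame(contig = ctg, start = c(0L, en[-length(en)]), end = en,
               level = r$values, stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, tracks)
  list(report = report, truth = truth,
       accessibility_track = binned_track(tr$contig, tr$start, tr$end,
                                          tr$level, NA_integer_))
}
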