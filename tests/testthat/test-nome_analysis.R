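test_that("channel splitting follows the HCG/GCH convention and excludes GCG", {
  g <- as_genome(a = "ACGT")
  r <- cytosine_report("a", 2L, "+", 5L, 5L, "CGT")
  sc <- split_channels(r, g, "GCMT")
  expect_equal(nrow(sc$intrinsic), 1L)   # A-C-G = HCG
  expect_equal(nrow(sc$induced), 0L)

  g2 <- as_genome(a = "AGCGT")
  r2 <- cytosine_report("a", 3L, "+", 5L, 5L, "CGT")
  sc2 <- split_channels(r2, g2, "GCMT")
  expect_equal(nrow(sc2$excluded), 1L)   # G-C-G is ambiguous
  expect_equal(nrow(sc2$intrinsic) + nrow(sc2$induced), 0L)

  # CCMT mode: CCG gives first C induced, second C intrinsic; disjoint
  g3 <- as_genome(a = "ACCGT")
  r3 <- cytosine_report("a", c(2L, 3L), "+", 5L, 5L, c("CCG", "CGT"))
  sc3 <- split_channels(r3, g3, "CCMT")
  expect_equal(sc3$induced$pos, 2L)
  expect_equal(sc3$intrinsic$pos, 3L)
  expect_equal(nrow(sc3$excluded), 0L)
})

test_that("channel split partitions every record, for both modes", {
  for (seed in 1:5) {
    g <- simulate_genome(5000, seed = seed)
    sim <- simulate_methylome(g, list(), seed = seed)
    for (mode in c("GCMT", "CCMT")) {
      sc <- split_channels(sim$report, g, mode)
      n <- nrow(sc$intrinsic) + nrow(sc$induced) + nrow(sc$excluded) +
        nrow(sc$other)
      expect_equal(n, nrow(sim$report))
      ki <- paste(sc$intrinsic$pos, sc$intrinsic$strand)
      kd <- paste(sc$induced$pos, sc$induced$strand)
      expect_equal(length(intersect(ki, kd)), 0L)
    }
  }
})

test_that("GCMT split excludes exactly the GCG cytosines", {
  g <- simulate_genome(5000, seed = 99)
  sim <- simulate_methylome(g, list(), seed = 99)
  sc <- split_channels(sim$report, g, "GCMT")
  cx <- classify_contexts(g)
  gcg_key <- with(cx[!is.na(cx$gcg) & cx$gcg, ], paste(contig, pos, strand))
  exc_key <- with(sc$excluded, paste(contig, pos, strand))
  expect_setequal(exc_key, gcg_key)
})

test_that("binning pools counts rather than averaging site levels", {
  r <- cytosine_report("c", 3L, "+", 8L, 2L, "NNN")
  b <- bin_levels(r, 10L)
  expect_equal(b$level, 0.8)
  expect_equal(b$start, 0L)

  # 1 meth of 1 plus 0 meth of 9: pooled level 0.1, not mean of levels 0.5
  r2 <- cytosine_report("c", c(3L, 7L), "+", c(1L, 0L), c(0L, 9L), "NNN")
  expect_equal(bin_levels(r2, 10L)$level, 0.1)

  # count conservation across bins
  set.seed(11)
  r3 <- cytosine_report("c", sample(1:1000, 300), "+", rpois(300, 5),
                        rpois(300, 5), "NNN")
  b3 <- bin_levels(r3, 25L)
  expect_equal(sum(b3$depth), sum(r3$meth + r3$unmeth))
  expect_equal(sum(b3$level * b3$depth), sum(r3$meth), tolerance = 1e-9)
})

test_that("binned levels of a constant methylome stay within binomial bounds", {
  g <- simulate_genome(10000, seed = 44)
  sim <- simulate_methylome(g, mtase_spec("N", target_offset = 0L,
                                          efficiency = 0.5,
                                          concentration = Inf),
                            coverage = coverage_spec(30, 0), seed = 44)
  b <- bin_levels(sim$report, 100L)
  se <- sqrt(0.5 * 0.5 / b$depth)
  expect_true(all(abs(b$level - 0.5) <= 3.5 * se))
})

test_that("aggregation orients offsets by anchor strand", {
  r <- cytosine_report("c", 108L, "+", 8L, 2L, "NNN")
  a <- anchor_set("c", 100L, "+")
  pr <- aggregate_profile(r, a, flank = 20L)
  expect_equal(pr$offset, 7L)           # 0-based site 107, anchor 100
  expect_equal(pr$mean_level, 0.8)

  a2 <- anchor_set("c", 100L, "-")
  pr2 <- aggregate_profile(r, a2, flank = 20L)
  expect_equal(pr2$offset, -7L)

  expect_error(aggregate_profile(r, anchor_set(character(0), integer(0),
                                               character(0)), 20L), "empty")
})

test_that("aggregation is invariant to anchor order and coordinate translation", {
  g <- simulate_genome(30000, seed = 55)
  sim <- simulate_methylome(g, mtase_spec("GC", efficiency = 0.7), seed = 55)
  anc <- anchor_set("contig_1", c(5000L, 12000L, 22000L), c("+", "-", "+"))
  p1 <- aggregate_profile(sim$report, anc, flank = 500L)
  p2 <- aggregate_profile(sim$report, anc[c(3, 1, 2), ], flank = 500L)
  expect_equal(p1, p2)

  shift <- 137L
  g2 <- as_genome(contig_1 = paste0(strrep("A", shift),
                                    as.character(g)[[1]]))
  r2 <- sim$report
  r2$pos <- r2$pos + shift
  a2 <- anc
  a2$pos <- a2$pos + shift
  p3 <- aggregate_profile(r2, a2, flank = 500L)
  expect_equal(p1$offset, p3$offset)
  expect_equal(p1$mean_level, p3$mean_level)
})

test_that("uniform methylation yields a flat profile at its level", {
  g <- simulate_genome(20000, seed = 61)
  sim <- simulate_methylome(g, mtase_spec("N", target_offset = 0L,
                                          efficiency = 0.5,
                                          concentration = Inf),
                            coverage = coverage_spec(30, 0), seed = 61)
  anc <- anchor_set("contig_1", c(5000L, 10000L, 15000L), "+")
  pr <- aggregate_profile(sim$report, anc, flank = 300L)
  expect_lt(abs(mean(pr$mean_level) - 0.5), 0.02)
})

test_that("periodicity estimation: cosine closed form and degenerate flagging", {
  off <- -600:600
  prof <- data.frame(offset = off,
                     mean_level = 0.5 + 0.3 * cos(2 * pi * off / 165),
                     n_sites = 1L)
  est <- estimate_periodicity(prof, 120L, 220L)
  expect_equal(est$period, 165)
  expect_true(est$confident)

  # a single missing stretch is interpolated, not fatal
  prof2 <- prof[abs(prof$offset) %% 7 != 3, ]
  expect_equal(estimate_periodicity(prof2, 120L, 220L)$period, 165)

  set.seed(3)
  noise <- data.frame(offset = off, mean_level = runif(length(off)),
                      n_sites = 1L)
  est2 <- estimate_periodicity(noise, 120L, 220L)
  expect_false(est2$confident)

  expect_error(estimate_periodicity(prof[1:100, ], 120L, 220L), "span")
})

test_that("accessible-region calling merges runs and honours min_len", {
  none <- binned_track("c", seq(0, 190, 10), seq(10, 200, 10), 0.1)
  expect_equal(nrow(call_accessible_regions(none, 0.5, 100L, 20L)), 0L)

  one <- binned_track("c", seq(0, 190, 10), seq(10, 200, 10),
                      c(rep(0.9, 20)))
  reg <- call_accessible_regions(one, 0.5, 100L, 20L)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$end - reg$start, 200L)

  # a short gap is bridged; a long one splits
  lv <- rep(0.9, 40)
  lv[20] <- 0.1
  gap1 <- binned_track("c", seq(0, 390, 10), seq(10, 400, 10), lv)
  expect_equal(nrow(call_accessible_regions(gap1, 0.5, 100L, 10L)), 1L)
  lv2 <- rep(0.9, 40)
  lv2[18:22] <- 0.1
  gap2 <- binned_track("c", seq(0, 390, 10), seq(10, 400, 10), lv2)
  expect_equal(nrow(call_accessible_regions(gap2, 0.5, 100L, 10L)), 2L)
})

test_that("planted NDRs are recovered with few false regions", {
  g <- simulate_genome(250000, seed = 71)
  anc_pos <- as.integer(seq(2500, 250000 - 2500, length.out = 50))
  anc <- anchor_set("contig_1", anc_pos, "+")
  sim <- simulate_nome(g, mtase_spec("GC", efficiency = 0.9),
                       chromatin_spec(anc, protection = 0.95),
                       coverage = coverage_spec(20), seed = 71)
  sc <- split_channels(sim$report, g, "GCMT")
  tr <- bin_levels(sc$induced, 10L)
  reg <- call_accessible_regions(tr, 0.5, 100L, 30L)
  ndr <- data.frame(start = anc_pos - 250L, end = anc_pos - 100L + 1L)
  hit <- vapply(seq_len(nrow(ndr)), function(i) {
    any(reg$start < ndr$end[i] & reg$end > ndr$start[i])
  }, logical(1))
  expect_gte(sum(hit), 45L)
  false_reg <- vapply(seq_len(nrow(reg)), function(i) {
    !any(reg$start[i] < ndr$end & reg$end[i] > ndr$start)
  }, logical(1))
  expect_lte(sum(false_reg), 2L)
})

test_that("track comparison: identity, null, and shared-signal cases", {
  set.seed(8)
  tr <- binned_track("c", seq(0, 4990, 10), seq(10, 5000, 10),
                     runif(500), depth = 50L)
  self <- compare_tracks(tr, tr)
  expect_equal(self$pearson, 1.0)

  n <- 2000
  a <- binned_track("c", seq(0, 10 * n - 1, 10), seq(10, 10 * n, 10),
                    runif(n), depth = 50L)
  b <- binned_track("c", seq(0, 10 * n - 1, 10), seq(10, 10 * n, 10),
                    runif(n), depth = 50L)
  null <- compare_tracks(a, b)
  expect_lt(abs(null$pearson), 3 / sqrt(n))

  expect_error(compare_tracks(a, binned_track("other", 0L, 10L, 0.5, 50L)),
               "share no bins")
})

test_that("two channels driven by one accessibility landscape correlate", {
  g <- simulate_genome(200000, seed = 83)
  anc <- anchor_set("contig_1", as.integer(seq(2000, 198000, by = 4000)), "+")
  chrom <- chromatin_spec(anc, protection = 0.9)
  nm1 <- simulate_nome(g, mtase_spec("CC", efficiency = 0.8), chrom,
                       coverage = coverage_spec(30), seed = 83)
  nm2 <- simulate_nome(g, mtase_spec("GC", efficiency = 0.8), chrom,
                       coverage = coverage_spec(30), seed = 84)
  # bins spanning ~3 nucleosome periods: the two channels sample the
  # footprint edges at different site positions, so sub-period bins carry
  # genuine within-bin heterogeneity that is not shared signal
  t1 <- bin_levels(split_channels(nm1$report, g, "CCMT")$induced, 500L)
  t2 <- bin_levels(split_channels(nm2$report, g, "GCMT")$induced, 500L)
  cmp <- compare_tracks(t1, t2, depth_floor = 5L)
  expect_gte(cmp$pearson, 0.8)
})
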