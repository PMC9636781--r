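---
title: "Determining MTase recognition sequences and NOMe-Seq analytics with methmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining MTase recognition sequences and NOMe-Seq analytics with methmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmotif)
```

# The problem

A DNA cytosine-C5 methyltransferase (MTase) deposits 5-methylcytosine (5mC)
at a short recognition sequence. When an MTase of unknown specificity is
expressed in *E. coli* and the host genome is read out by whole-genome
bisulfite sequencing (WGBS), every cytosine in the genome becomes an assay
point: target cytosines are methylated at high level, everything else stays
near the bisulfite non-conversion background. methmotif determines the
recognition sequence from such data, and provides the downstream analytics
needed when a short-motif MTase is used as a chromatin-accessibility probe
(NOMe-Seq): separating intrinsic CG methylation from enzyme-induced
methylation, binned tracks, aggregation profiles around genomic anchors,
nucleosome periodicity, and a site census that converts motif frequency
into analytical resolution.

# The methylation-weighted PWM and M-logo

For every cytosine $k$ with methylation level $m_k$ (methylated reads over
total reads) we take the sequence window of length $2l+1$ centred on it
(minus-strand cytosines contribute the reverse complement, so windows
always read 5'→3' on the methylated strand). The methylation-weighted
position weight matrix is

$$M_{ij} \;=\; \frac{1}{N}\sum_{k=1}^{N} m_k \, I_i\!\left(S_{K+j}\right),$$

where $i$ ranges over A/C/G/T, $j \in [-l, l]$ is the offset from the
centre, $S_{K+j}$ is the base at offset $j$ of window $k$, $I_i$ is the
indicator, and $N$ is the number of contributing windows. The weighting is
the whole point: an unmethylated window contributes nothing, so base
composition at informative offsets reflects the windows the enzyme actually
methylated. Normalising each offset,

$$f_{ij} = \frac{M_{ij}}{\sum_i M_{ij}},$$

and the logo follows from the Shannon entropy and an information content
with a fixed small-sample constant:

$$H_j = -\sum_i f_{ij}\log_2 f_{ij}, \qquad
  R_j = \log_2(4) - H_j - 0.541, \qquad
  \mathrm{height}_{ij} = f_{ij}\,R_j.$$

Two conventions deserve comment.

* **Sum, not product.** The statistic is necessarily a sum over windows.
  A product over per-window terms would be annihilated by any single
  unmethylated window (a term of zero), which contradicts both the
  "weighted frequency" semantics and the normalisation step that follows;
  methmotif implements the sum.
* **$N$ cancels.** Whether $N$ counts contributing windows (as here) or
  all genomic cytosines only rescales $M$ by a constant per matrix; $f$,
  $H$, $R$, heights and the consensus are identical either way. The same
  cancellation makes every logo quantity invariant under a global rescaling
  of methylation levels, which the test suite asserts.
* **0.541 is a literal.** The constant is kept as printed, not recomputed
  as a small-sample correction for the window count at hand; $R_j$ is not
  clamped at zero, so uninformative offsets sit near
  $2 - 2 - 0.541 = -0.541$ bits.

## Consensus calling

The collapse of a logo to an IUPAC string is a deliberately simple rule:
the consensus span is the minimal contiguous offset interval containing the
centre and every offset with $R_j \ge \theta$; inside the span, offsets
below $\theta$ print as `N`; at informative offsets, bases are accumulated
in decreasing $f_{ij}$ until the cumulative frequency reaches $\kappa$
(ties included), and the base set prints as its IUPAC code.

**Why $\theta = 0.05$ bits.** The threshold separates two well-defined
populations. Offsets carrying no recognition signal have near-uniform
methylation-weighted frequencies and sit at $R_j \approx -0.541$ bits —
far below any positive threshold. The weakest genuinely informative
offsets arise for *rare* motifs: a 4-bp recognition sequence on a uniform
genome makes only ~1/64 of cytosines targets, so background methylation of
the other 63/64 dilutes $f$ at the informative offsets. At a realistic
non-conversion background the degenerate position of such a motif (e.g.
the R of RGCA) still carries $R_j \approx 0.1$ bits. A threshold of 0.05
bits sits between the two populations with a comfortable margin on each
side; raising it towards the height of fully conserved positions
(~1.4 bits) would silently truncate rare or degenerate motifs.
$\kappa = 0.85$ admits a second base only when the first truly fails to
explain the methylated windows, which turns 50/50 two-base positions into
their two-letter code (Y, R, ...) while keeping singleton positions
singleton.

**Window half-width $l = 5$.** The longest recognition sequences seen for
cytosine-C5 MTases of this class are 4 bp; an 11-mer window leaves margin
on both sides, and the minimal-span rule trims uninformative flanks, so a
larger $l$ costs only computation.

**Depth filter.** Whether the original per-cytosine tables carried a
minimum-depth filter is not documented for this class of experiment;
methmotif exposes `min_depth` (default 5 reads) and skips zero-coverage
records, whose level is undefined.

# Genome census and analytical resolution

`count_motif_targets()` counts the *target cytosines* of a motif across
both strands with overlaps allowed; a palindromic motif such as CG or GC
therefore counts two targets per duplex site (which is what makes the
published CG count for hg19 even). Analytical resolution is the mean
spacing of assay points, genome size over site count, rounded half away
from zero — all five published hg19 rows (55, 72, 13, 13, 10 bp) are
insensitive to the half-rounding rule. Coverage summaries count sites at
or above a read-depth threshold (default 10).

The methylation-sensitive digest (`digest_in_silico()`) implements the
wet-lab logic used to assay MTase activity: a site occurrence is cut
unless any of its blocking cytosines is methylated. The population-level
stand-in for the molecule-level assay is a level threshold (default 0.5).
Built-ins cover the two assay enzymes, HaeIII (GG^CC, blocked by 5mC of
the first C of its CC on either strand) and HpaII (C^CGG, blocked by
either of its cytosines); both are overridable via
`restriction_enzyme()`.

# NOMe-Seq channel separation

A GC-methylating probe (GCMT) collides with intrinsic CG methylation at
the GCG trinucleotide, where the causative enzyme cannot be identified;
the standard convention is to read intrinsic methylation from HCG sites
and induced methylation from GCH sites, excluding GCG entirely
(H = A/C/T). A CC-methylating probe (CCMT) has no such overlap: the CC
target set and the CG target set are disjoint because they differ in the
base following the cytosine, so nothing is excluded and every CG and every
first-C-of-CC is usable — the source of the CC probe's resolution
advantage (10 bp vs 13 bp in hg19). `split_channels()` implements both
conventions as a strict partition (intrinsic / induced / excluded /
other), which the tests assert on random genomes.

Binned tracks are coverage-weighted (pooled counts), the standard WGBS
convention, because it is robust at shallow depth. Aggregation profiles
use unweighted per-site means across anchors so a single deep site cannot
dominate a position. Periodicity is estimated as the autocorrelation
argmax of the mean-subtracted, linearly interpolated profile over a lag
window (default 120–220 bp); a profile whose best autocorrelation falls
below 0.1 is flagged low-confidence rather than trusted. The
accessible-region caller is a threshold segmenter over binned induced
levels (runs ≥ `min_len`, gaps ≤ `merge_gap` merged) — a transparent
stand-in for a statistical peak caller, and documented as such.

# What the synthetic generator emulates

`simulate_genome()` draws i.i.d. or first-order Markov sequence.
`simulate_methylome()` plants an MTase specificity: target sites (found by
the same both-strand convention as the census) receive Beta-distributed
levels around the enzyme's efficiency; all cytosines carry a non-conversion
background; read depth is i.i.d. Poisson and observed methylated counts are
Binomial. Redundant methylation causes combine by `max`, not addition,
because levels are probabilities of the same mark. An optional per-context
override reduces efficiency at a named trinucleotide (e.g. weak CCC
methylation); it is off by default. `simulate_nome()` adds a chromatin
layer: promoter anchors carry nucleosome-depleted regions (default
−250..−100 bp, strand-oriented), 147-bp footprints tile outward from the
NDR edges at the repeat length (default 165 bp), and induced methylation is
scaled by accessibility (1 in NDRs and linkers, 1 − protection under
footprints). The intrinsic CG landscape is a two-state domain model
(highly methylated regions at mean 0.85, partially methylated domains at
mean 0.4, geometric lengths) and is deliberately insensitive to
accessibility. Giving `intrinsic_spec()` its own seed makes the landscape
a property of the "sample", so a treated and an untreated library of the
same genome share it exactly while read sampling stays independent.

Default study conditions used by the tests and the acceptance script:
planted-motif battery on 1 Mb uniform genomes at efficiency 0.85 and
coverage λ = 20 (three seeds per motif, eight motifs: TCTG, CG, CC, CNG,
TCG, GCY, GC, RGCA — the degenerate form RGCA is used for the
R-containing motif); NOMe recovery on 400 kb with anchors every 3 kb;
intrinsic fidelity on 500 kb at λ = 25 with 10-kb bins. The background
non-conversion default is 0.002 (0.2%), typical of modern lambda-spiked
post-bisulfite libraries.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: read-level autocorrelation and mapping
bias, bisulfite conversion chemistry, PCR duplicates, CpG-island-like
compositional structure (unless supplied via the transition matrix),
nucleosome positional jitter (off by default so the periodicity test is
sharp; a jitter SD is exposed), and the fuzziness of real NDR boundaries.
Recovery rates measured here are upper bounds relative to real libraries.

# Numerical choices and degenerate inputs

* $0 \log 0 := 0$ in the entropy; offsets with an all-zero matrix column
  are flagged degenerate, carry `H = NA`, and are excluded from consensus
  calling; a fully degenerate logo (no methylation anywhere) is an error,
  not a silent "C".
* Windows truncated at contig edges or containing `N` are never
  constructed; zero-coverage records are skipped before windowing.
* Consensus ties at the $\kappa$ cutoff include all tied bases
  (tolerance 1e−12), so exact 50/50 positions are stable.
* Resolution rounds half away from zero; base R's banker's rounding would
  change no published value but would be a surprising convention.
* Bin levels and track comparisons drop bins below a depth floor
  (default 5 pooled reads) before correlating; inner join on bin
  coordinates — a bin covered in only one track is dropped, not imputed.
* All generators restore the caller's RNG state; sub-streams are derived
  per component so adding an MTase to a simulation does not perturb the
  intrinsic landscape or coverage draws.

# Problem sizes

The shipped tests run the motif battery at the full 1 Mb per instance
(24 instances), the NOMe recovery at 400 kb with 133 promoters, and the
intrinsic-fidelity comparison at 500 kb; unit tests use 2–200 kb genomes.
These sizes were chosen so that every stochastic assertion has a
comfortable margin over its sampling noise while the whole suite stays
fast enough to run routinely.

# Known limitations

* The consensus caller reports a single contiguous IUPAC string; bipartite
  or gapped specificities longer than the window are out of scope.
* The hg19 census numbers are reproduced as arithmetic on the published
  site counts; recomputing the counts themselves requires the hg19
  assembly and depends on contig selection and masking conventions that
  are not part of this package's tests.
* The accessible-region segmenter has no statistical model; it is a
  transparent threshold rule, not a replacement for a peak caller with
  background estimation.
* Aggregation-profile flank, smoothing (none) and weighting are analysis
  choices of this package, exposed as parameters, not facts about any
  particular published pipeline.
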