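Package: methmotif
Title: Methyltransferase Recognition-Sequence Discovery and NOMe-Seq Analytics from Per-Cytosine Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines DNA methyltransferase (MTase) recognition sequences
    from whole-genome bisulfite sequencing data via a methylation-weighted
    position weight matrix (PWM-M), its information-content logo (M-logo),
    and an IUPAC consensus caller. Also provides a genome-wide cytosine
    context census with analytical-resolution and coverage summaries, an
    in-silico methylation-sensitive restriction digest, NOMe-Seq channel
    separation (intrinsic CG versus MTase-induced methylation), binned
    methylation tracks, anchor-centred aggregation profiles, nucleosome
    periodicity estimation, and a synthetic-methylome generator so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
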