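Package: telomark
Title: Motif-Based Quantification of Chromatin Marks at Telomeres from
    ChIP-Seq Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies histone-modification enrichment at plant telomeres
    from ChIP-seq read sets while controlling for interstitial telomeric
    sequences (ITSs). Classifies reads by exact overlapping occurrences of
    telomeric 35-mers ((CCCTAAA)5 / (TTTAGGG)5) and centromeric 178-bp
    satellite motifs (Cen1 / Cen2), computes input-normalized enrichment
    ratios relative to the whole genome and to the satellite repeats,
    derives the fraction of reads mapping to unique sequences (RMUS), and
    pools values across studies with normality-gated parametric or
    non-parametric tests. Includes a synthetic genome and read simulator
    with known telomere, ITS and satellite architecture so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
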