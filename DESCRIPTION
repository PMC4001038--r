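Package: tnfit
Title: Transposon Mutant Fitness Profiling for Pooled Growth Competitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene fitness estimation from pooled transposon mutant growth
    competitions in bacteria, implementing two complementary read-outs: a
    barcoded mutant pool (TagModule uptag/downtag) microarray pipeline with
    low-signal filtering, per-pool median-zero normalization, gene-level
    averaging, chromosomal-position and kernel-density mode-zero correction,
    and strain/operon correlation quality metrics; and an insertion-density
    (Tn-seq style liquid enrichment) pipeline that scores genes by the log2
    ratio of unique insertion density in the 5-85% coding window to the
    genome-wide density, with a population-doublings estimator. A growth
    competition simulator generates annotated genomes, overlapping barcoded
    pools, dense insertion libraries, noisy intensity tables and multinomial
    read counts with known ground truth, including strong-selection "jackpot"
    regimes. Multi-condition reports apply anion-consistency candidate rules
    and cross-genome homolog joins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
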