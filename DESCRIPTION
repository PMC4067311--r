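Package: CNVpop
Title: Consensus CNV Discovery, Population Screening and qPCR Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline for SNP-array copy number variant
    (CNV) calls in small population cohorts: per-call quality filters and
    centromere/telomere exclusion zones, multi-algorithm (2-of-3) consensus
    merging per genome, cross-sample copy number variable region (CNVR)
    construction with carrier-frequency statistics, reciprocal-overlap
    screening against tiered reference CNV catalogues to identify
    population-specific variants, gene-overlap annotation with an exact
    gain/loss sign test, and a comparative-CT (2^-ddCt) qPCR copy-number
    validator. Includes seeded simulators for cohorts, imperfect callers,
    reference catalogues and Ct replicates so every stage can be tested
    closed-loop against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
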