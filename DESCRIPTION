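Package: methylripe
Title: Tissue-Resolved Whole-Genome Bisulfite Methylome Analysis of Fruit Ripening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for per-cytosine bisulfite count data from whole-genome
    bisulfite sequencing (WGBS) of fruit tissues across ripening stages.
    Provides cytosine-report reading and depth filtering, chloroplast-based
    bisulfite conversion QC, genome-binned and feature-anchored methylation
    profiles, differential methylation calling (per-site binomial
    likelihood-ratio tests with context-specific thresholds, sliding-window
    region construction), tissue-specificity classification of
    hypermethylated regions, a promoter-bin classifier of
    methylation-responsive genes integrated with differential-expression
    calls, and a beta-binomial methylome simulator with planted effects and
    recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    tools,
    jsonlite,
    methods,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
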