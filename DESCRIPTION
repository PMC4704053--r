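Package: methylscape
Title: Whole-Genome Bisulfite Methylome Analysis with Differential
    Methylation and Expression Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of whole-genome bisulfite sequencing (WGBS) data
    from per-site cytosine pileups: binomial methylcytosine calling
    against the bisulfite non-conversion rate with Benjamini-Hochberg
    FDR control, CG/CHG/CHH context extraction, methylation landscapes
    (sliding windows, chromosome profiles, gene metaprofiles),
    Fisher's-exact differential methylation of gene regions and windows
    with RKTM normalization, no-replicate differential expression
    (Audic-Claverie), joint methylation-expression filtering, and
    methylation ratios at miRNA precursor loci. Includes a simulator
    for bisulfite pileups with known truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    S4Vectors,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
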