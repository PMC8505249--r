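Package: celldmr
Title: Cell-Type-Specific Promoter Methylation Analysis from Enrichment Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cell-type-specific promoter DNA methylation
    from MBD-enrichment tiling-array signal: per-sample methylated-region (MR)
    calling against a whole-genome-amplified reference, duplicate-replicate
    differentially methylated region (DMR) identification with direction,
    CpG-island and gene-structure context classification, gene-set enrichment
    over user-supplied GMT collections, directional overlap against auxiliary
    interval tracks (drug-induced DMRs, hydroxymethylated regions), per-CpG
    validation against bisulfite count tables, and a promoter-based GWAS-locus
    enrichment test with a resampling null. A synthetic-data generator emulates
    a promoter tiling array with planted methylation structure so the whole
    analysis runs with ground truth and no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
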