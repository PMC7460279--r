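Package: rohdiv
Title: Runs of Homozygosity, Genomic Inbreeding and Population Structure
    from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide diversity analysis of diploid biallelic
    SNP-array genotypes in structured populations (breeds): PED/MAP and
    genotype-table input, marker and sample quality control, per-breed
    diversity indices (MAF, observed/expected heterozygosity, the
    excess-homozygosity inbreeding coefficient F_HOM), constraint-based
    detection of runs of homozygosity (ROH) with the genomic inbreeding
    coefficient F_ROH and length-class summaries, per-SNP ROH incidence
    tracks with autozygosity-island detection and interval annotation,
    identity-by-state and Reynolds genetic distances with classical
    multidimensional scaling and neighbor-joining trees, and a seeded
    synthetic-genotype generator with truth tables for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ape,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
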