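Package: indelgt
Title: Genotyping Insertions and Deletions from Paired-End Read Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls genotypes (0/1/2) of known insertions and deletions (>= 50 bp)
    in diploid individuals from coordinate-sorted paired-end alignments. For each
    (individual, site) pair it tallies discordant and concordant encompassing read
    pairs, split and soft-clipped reads at the breakpoints, fully mapped spanning
    reads, single-end-mapped pairs and region read depth, normalizes the tallies by
    local coverage, and classifies the resulting feature vectors with a support
    vector machine tuned by grid search and stratified cross-validation. Includes a
    seed-stable diploid paired-end read simulator for generating labeled training
    data, and evaluation utilities: length- and frequency-stratified genotype
    accuracy, trio Mendelian-discordance metrics, and reproducible read
    downsampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    jsonlite,
    e1071,
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    Biostrings,
    vcfR,
    optparse
Config/testthat/edition: 3
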