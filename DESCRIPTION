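Package: dualcons
Title: Dual Redundant Sequencing Consensus for Full-Length HLA Allele
    Characterisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for characterising full-length HLA
    alleles from two independent sequencing technologies. Simulates
    heterozygous amplicon samples with platform-specific read sets
    (accurate 251 bp paired short reads; multi-kilobase long reads with
    indel-dominated error above 10 percent), derives independent
    short-read and long-read consensus sequences, reconciles their
    disagreements against the closest reference allele with a rule
    engine, resolves phase-undefined and homopolymer-ambiguous cases by
    clustering long reads per allele and polishing each haplotype
    consensus with short reads, annotates the final sequence (gene-model
    transfer, difference enumeration, null and questionable-expression
    classification), and writes EMBL-style submission flat files and
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
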