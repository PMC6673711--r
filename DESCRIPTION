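Package: cnvwatch
Title: Read-Depth Copy Number Variant Discovery, Allele Typing and
    Selection Scans for Population Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects amplification copy number variants (CNVs) from
    short-read sequencing coverage in population cohorts. Counts reads in
    non-overlapping 300-bp windows, normalizes for GC content to a
    copy-number scale, infers per-window copy number states with a
    Gaussian hidden Markov model, and filters calls by likelihood ratio,
    sample coverage variance, cross-sample breakpoint matching and
    population frequency. Includes permutation tests for CNV enrichment
    in heterochromatin, genic and detoxification-gene regions; typing of
    distinct CNV alleles from discordant read pairs and breakpoint
    soft-clipped reads with allele-specific copy number estimation and
    Hardy-Weinberg genotype filtering; and haplotype-based selection
    scans (extended haplotype homozygosity, pairwise shared haplotype
    length, haplotype clustering). A synthetic-cohort generator with
    known truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
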