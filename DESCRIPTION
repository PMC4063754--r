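Package: polyase
Title: Allele-Specific Expression in Polyploids from RNA-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures allele-specific expression (ASE) in polyploid
    organisms from RNA-seq data aligned to a transcriptome reference.
    Per-strain consensus genotypes are called from samtools mpileup text
    with conservative coverage, base-quality, allele-frequency, exact-test
    and strand filters; positions at which exactly one parental haplome
    carries a nucleotide absent from all others (discriminatory SNPs) are
    identified; transcript expression is summarised as the geometric mean
    of coverage depth, normalised across samples by median-of-ratios size
    factors, and apportioned between alleles from the read fractions
    observed at discriminatory SNPs. Includes classification of allelic
    imbalance (equality test, coefficient of variation, per-allele
    up/down categories and expression-change quadrants), a paired-end
    read simulator with known allele fractions for parameter-recovery
    validation, and an end-to-end pipeline driver with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
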