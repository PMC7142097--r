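Package: meganumt
Title: Trio Screening for Mega-NUMTs that Mimic Biparental mtDNA Inheritance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects rare, large nuclear insertions of concatenated
    mtDNA-derived sequence (mega-NUMTs) that masquerade as paternally
    inherited mitochondrial heteroplasmy in family trio whole-genome
    sequencing. Implements mtDNA variant filtering and homoplasmy rules,
    a trio-based screen for mixed heteroplasmic haplotypes, NUMT and
    breakpoint detection from discordant read pairs and split reads,
    copy-number estimation for concatemer insertions, modelling of the
    mixed-haplotype allele fraction as a function of nuclear and
    mitochondrial sequencing depth, exact binomial transmission
    statistics, and a seeded synthetic-cohort generator with ground-truth
    labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics
Config/testthat/edition: 3
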