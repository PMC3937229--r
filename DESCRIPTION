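Package: cisSelect
Title: Common Insertion Site Detection and Selection Statistics for
    Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of retroviral insertional mutagenesis
    screens starting from mapped insertion sites. Implements common
    insertion site (CIS) detection by multi-scale Gaussian kernel
    convolution with Monte-Carlo calibration against a random-integration
    null, the fixed-window cluster rule used for vector integration sets,
    orientation-bias testing with Benjamini-Hochberg correction,
    transcription-start-site distance profiles, saturation (coverage
    accrual) analysis with pseudo-kernels, genomic-bin and gene-set
    enrichment, genotype comparisons, and a synthetic integration-cohort
    generator with a truth table for recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
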