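Package: ldbscreen
Title: Target-Gene Selection, Binding-Site Enrichment and Modifier-Screen
    Statistics for CHIP/LDB Transcription Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying downstream target genes of
    CHIP/LDB transcription complexes in Drosophila and characterising their
    regulation. Selects differentially expressed genes from two-channel
    microarray data (print-tip loess and quantile normalisation, per-gene
    fixed-effect ANOVA, Benjamini-Hochberg correction); tests
    transcription-factor binding-site over-representation in upstream
    regions by a threshold-scan hypergeometric method and by a hidden
    Markov model promoter-scoring method; and implements the statistics of
    dominant-modifier genetic screens (ordinal wing-notching severity
    distributions and binomial scutellar-bristle duplication tests),
    including Table-style interaction summaries. A seeded synthetic-data
    generator reproduces the statistical structure each stage assumes so
    the whole pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics,
    Biostrings,
    limma,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
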