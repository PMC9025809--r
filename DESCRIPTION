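Package: oviso
Title: Long-Read Isoform Catalogs, Splicing Events and Differential
    Analyses for Sheep Muscle Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for updating a genome annotation from full-length
    non-concatemer (FLNC) long-read isoform candidates, classifying
    alternative-splicing events between isoforms of a locus, calling
    differentially expressed isoforms and differential ChIP-seq peaks with
    a negative-binomial model, annotating peaks to genomic feature
    categories, testing gene-set overlaps with the exact hypergeometric
    tail, and computing two-group trait statistics and 2^-ddCt relative
    expression from qPCR cycle thresholds. A synthetic-data generator
    emulates the two-crossbred-group sheep muscle study design (n = 3 vs 3)
    with ground-truth tables so the whole pipeline is testable without raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
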