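Package: pecknet
Title: Structural-Variant Association and Gene-Network Analysis for
    Feather-Pecking Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for mapping structural variants (SVs) and
    tandem repeats (TRs) to a behavioural phenotype and to gene expression.
    Implements SURVIVOR-style merging and filtering of multi-caller SV call
    sets, mixed-linear-model genome-wide association with
    leave-one-chromosome-out genomic relationship matrices and REML variance
    components, sample-size-weighted meta-analysis across study designs,
    expression GWAS, association-weight-matrix construction with PCIT
    partial-correlation network inference, and position-weight-matrix
    scanning with gene-coverage enrichment tests for transcription-factor
    binding sites.  A seeded synthetic-data generator emulates the
    statistical structure of a divergently selected chicken population
    (F2 cross and half-sib families), so the whole pipeline runs and is
    testable at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
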