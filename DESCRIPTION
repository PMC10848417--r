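Package: rareclone
Title: Rare-Subclone Detection and Sequential Mutation-Acquisition
    Modeling for Paired Primary-Metastasis Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for deciding whether mutations private to a
    metastatic recurrence pre-existed within rare subclones of the
    antecedent primary tumor, using UMI error-corrected ultra-deep
    sequencing (UDS-UMI) variant tables. Provides binomial detection-power
    statistics (minimum detectable VAF and cancer cell fraction at a
    stated confidence), VAF-to-CCF conversion with allele multiplicity
    uncertainty and Beta posterior draws, FFPE deamination artifact burden
    profiling with estimation of the fraction of C>T artifacts removed by
    uracil-DNA glycosylase (UDG) treatment, pigeonhole-principle
    co-clonality tests, false-positive significance tests against
    background rare-subclonal mutation burden (likelihood and sample
    permutation), a driver-versus-passenger sequential
    mutation-acquisition likelihood framework, and a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Biostrings
Config/testthat/edition: 3
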