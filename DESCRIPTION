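Package: smrnade
Title: Small RNA Sequencing Profiling and Exact-Test Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for insect small RNA sequencing studies:
    read filtering with per-category accounting, adapter trimming and tag
    collapsing, hierarchical annotation of clean tags against reference
    classes, transcripts-per-million normalization, an exact count-based
    (Audic-Claverie type) differential expression test with Bonferroni
    correction, novel miRNA candidate filtering with a dinucleotide-preserving
    shuffle test and a base-pair stacking folding model, target-set
    intersection across predictors, and 2^-ddCt qPCR concordance analysis.
    Includes a seeded synthetic-data generator that emulates the read-length
    and class structure of insect small RNA libraries so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
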