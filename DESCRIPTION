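Package: hicdelta
Title: Differential Hi-C Analysis of Chromatin Loops and A/B Compartments
Version: 0.1.0
Authors@R:
    person("hicdelta", "developers", email = "hicdelta@example.org",
           role = c("aut", "cre"))
Description: Tools for paired-condition Hi-C analysis of 3D genome
    reorganization: read-pair filtering (uniqueness, positional
    de-duplication, restriction-fragment assignment, inward/outward
    distance rules), sparse contact-matrix construction and iterative
    balancing, distance-decay expected models, local-background chromatin
    loop scoring, insulation-based TAD profiling, A/B compartment calling
    from the O/E correlation matrix with per-bin switch testing,
    Z-score differential loop calling with loop-size and set-overlap
    statistics, integration of loop and compartment calls with
    differential gene expression (TSS linkage, Fisher and hypergeometric
    tests, delta-delta-Ct quantification), spike-in normalization of
    ChIP-seq tag counts, and a synthetic-data generator that plants
    compartments, TADs, loops, coupled expression, and spike-in counts
    with a full ground-truth record for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
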