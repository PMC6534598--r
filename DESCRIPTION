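Package: tcbarrier
Title: Genetic Models and Scoring Statistics for the Tcb1 Maize-Teosinte
    Crossing Barrier
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetic toolkit for the gametophytic
    cross-incompatibility system at the maize/teosinte Tcb1 locus. Provides a
    deterministic model of the four Tcb1 haplotypes (pollen acceptance rules,
    two-locus gamete frequencies, linked-marker segregation expectations),
    stochastic simulators of mixed-pollination tests, open-pollinated mutant
    screens and mop1 reversion experiments, the ear-scoring statistics used to
    detect barrier function (two-tailed exact test on 2x2 kernel tables,
    barrier-strength odds ratio, two-tier ear classification, recombinant
    cosegregation, exact-binomial screen outlier flagging), qRT-PCR relative
    expression with an expression-threshold barrier model, and molecular
    divergence dating of aligned coding-sequence pairs. Includes seeded
    synthetic-data generators for every analysis stage and a scenario runner
    producing machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
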