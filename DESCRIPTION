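Package: propcomm
Title: Differential Proportion Analysis and Ligand-Receptor Communication
    Networks for Single-Cell Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Permutation-based testing of changes in cell-cluster proportions
    between conditions in single-cell RNA-seq cohorts (differential proportion
    analysis), with simulation benchmarks against per-cluster Fisher's exact
    tests, and a four-layer weighted ligand-receptor network for scoring
    cell-cell communication between populations, with an empirical permutation
    null and Benjamini-Hochberg correction. Includes a synthetic-data generator
    with planted ground truth (multinomial cluster memberships, negative-
    binomial expression with planted ligand/receptor up-regulation) and
    readers and writers for the plain-text interchange formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
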