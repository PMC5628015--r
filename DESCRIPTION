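Package: dielNet
Title: Circadian-Guided Co-Expression Network Analysis of Diel Stress Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Condition-specific signed weighted co-expression networks for
    diel (day/night cycle) transcriptome time courses, with module detection by
    adaptive branch cutting on the topological overlap dissimilarity, module
    eigengene summaries, module-trait correlation against diel physiology
    (assimilation, stomatal conductance, PSII efficiency, non-structural
    carbohydrates, intrinsic water-use efficiency), a nonparametric
    rank-based rhythmicity test with an exact permutation null (a JTK-CYCLE
    style procedure), cosinor amplitude estimation, and a two-criterion
    selection of stress-responsive transcripts (gained rhythmicity or
    amplitude change). Includes probe-count (NanoString-style) housekeeping
    normalization and modified Z-score QC, hypergeometric over-representation
    testing, and a seeded synthetic-data generator with planted ground truth
    so every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
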