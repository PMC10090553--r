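Package: codepnet
Title: Co-Dependency Screening and Differential Correlation Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for nominating context-specific cancer vulnerabilities from
    functional genomic screens and cohort transcriptomes. Stratifies cell lines
    by a small-cell neuroendocrine (SCN) phenotype score, screens genome-wide
    dependency-score matrices (DEMETER2- or CERES-style) for genes whose
    perturbation profile correlates with an anchor gene within a phenotype
    group, filters candidates through a significance/rank/transcription-factor
    funnel with cross-group exclusion, builds per-cohort anchor-centred
    correlation gene networks from expression matrices, ranks genes by the
    difference of their anchor correlation between two disease states, and
    runs preranked gene-set enrichment (weighted running-sum statistic,
    gene-label permutation null, normalized enrichment scores and
    sign-stratified false discovery rates) on the differential profile. A
    synthetic-data module generates dependency matrices, phenotype
    annotations, two-cohort expression matrices with planted correlation
    blocks, and gene-set collections with recorded ground truth, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
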