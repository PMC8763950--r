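Package: methylaging
Title: Age-Structured DNA Methylome Analysis and Epigenetic Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing age-structured bisulfite-sequencing
    methylomes: reading Bismark coverage files into coverage-filtered
    methylation matrices, per-sample Shannon-entropy and methylation-level
    summaries, genome-wide CpG-age correlation screens with Bonferroni
    partitioning and PCA, strand-aware promoter and gene-body correlation
    profiling against a GTF annotation, elastic-net epigenetic clocks with
    nested cross-validation and age-acceleration statistics, and
    cross-species comparison of clock-site methylation trajectories on a
    relative-age scale. A seeded synthetic-cohort generator emulating
    age-increasing, age-decreasing and stable CpG classes with binomial
    read sampling makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    glmnet,
    rtracklayer,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
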