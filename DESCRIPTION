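Package: immunometh
Title: Immune Microenvironment Profiling of Tumors from DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Profiles the tumor immune microenvironment from Illumina-style
    methylation beta-value matrices. Derives immune cell type-specific promoter
    CpG signatures from reference methylomes (Fisher exact differential
    methylation among immune cell types, hypermethylation filtering against
    nonimmune cells and tumor lines, best-CpG-per-gene selection), consensus-
    clusters tumor cohorts over the selected CpGs, classifies new samples by
    Kendall correlation to per-cluster methylation centroids, computes
    per-cell-type methylation and expression scores, calls PTEN promoter
    hypermethylation and integrated alteration events, and provides the
    accompanying cluster-level statistics (Kruskal-Wallis with Dunn post hoc
    and per-comparison FDR, categorical associations, Cox regression and
    Kaplan-Meier analysis). A seeded synthetic-data generator emulates
    reference panels, purity-weighted tumor cohorts with planted infiltration
    strata, linked expression, survival and PTEN lesions, so the full pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
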