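Package: cellclock
Title: Cell-Type-Specific Transcriptomic Aging Clocks from Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cell-type-specific transcriptomic aging clocks from
    single-nucleus RNA-seq count data. Cells are bootstrap-aggregated into
    pseudocells within each sample and cell-type stratum, an elastic-net
    regression of chronological age on normalized pseudocell expression is
    trained per cell type, and clocks are validated by leave-pair-out
    cross-validation. Trained clocks predict the transcriptional age of
    treatment groups; rejuvenation is tested per cell type by one-way ANOVA
    with Tukey's multiple-comparison correction on per-sample mean predicted
    ages, and clock-driver genes are extracted as features with non-zero
    variable importance. A negative-binomial single-nucleus count simulator
    with planted age-dependent gene programs and configurable rejuvenation
    provides ground-truth data for end-to-end validation, alongside
    10x-style Matrix Market input/output and a full pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
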