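Package: apscore
Title: Astrocytoma Progression Scoring from Gene Expression
Version: 0.1.0
Authors@R: person("APScore", "Developers", email = "apscore@example.org",
    role = c("aut", "cre"))
Description: Constructs and evaluates a two-gene-set prognostic score for
    astrocytoma (the AP score). A five-criterion filter cascade selects
    progression genes from a gene-by-sample log2 expression matrix with
    normal tissue, lower-grade glioma and glioblastoma samples; single-sample
    gene-set enrichment (ssGSEA) of the positive- and negative-regulator
    sets yields a per-sample score whose difference is the AP score.
    Includes Kaplan-Meier, log-rank with Mantel-Haenszel hazard ratio and
    Cox proportional-hazards regression written from explicit formulas,
    association statistics (ANOVA, Fisher/chi-square, Pearson, paired t,
    outcome ROC/AUC, mutation and copy-number group comparisons, immune
    gene-set correlation), a synthetic-cohort generator that emulates the
    statistical structure of a TCGA-style glioma training cohort, and a
    command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
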