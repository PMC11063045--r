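Package: screendca
Title: Accuracy Evaluation and Decision Curve Analysis for Community
    Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating multi-class disease screening tests and
    for deciding whether deploying them is worthwhile. Computes per-class
    sensitivity, specificity and Youden's index from record-level
    predictions or from published contingency counts; compares several
    screening models with Pearson chi-square or exact (Fisher /
    Freeman-Halton) tests followed by Bonferroni-corrected post-hoc
    pairwise comparisons; and runs decision curve analysis (net benefit
    across probability thresholds, against treat-all and treat-none) on a
    hypothetical cohort, both in closed form and empirically on simulated
    record tables. Includes a seeded synthetic screening-cohort generator
    with configurable prevalences and classifier operating points, and a
    YAML-driven pipeline that ties the stages together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
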