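Package: her2lowsig
Title: Gene Expression Signature Scoring for HER2-Low Breast Cancer
Version: 0.1.0
Authors@R:
    person("her2lowsig", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates a transcriptomic classifier for HER2-low
    breast cancer (immunohistochemistry 1+, or 2+ without ERBB2
    amplification). Provides one-vs-rest differential-expression screening of
    HER2 IHC categories with a fold-change filter, Wilcoxon rank-sum testing
    and Bonferroni adjustment; Venn-style selection of category-specific
    genes; construction of a first-principal-component weighted signature
    score from standardized expression; and an evaluation battery with
    Kruskal-Wallis and post hoc rank-sum comparisons, ROC AUC with DeLong
    confidence intervals, Youden-index cutoff selection, and full-order
    partial-correlation networks. A multi-cohort synthetic expression
    generator with planted category-specific genes makes every stage testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
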