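# her2lowsig

Gene-expression signature scoring for **HER2-low breast cancer** — tumors
scoring 1+ at HER2 immunohistochemistry (IHC), or 2+ without *ERBB2*
amplification. These tumors are eligible for HER2-directed antibody–drug
conjugates, but the IHC read in exactly the 0 / 1+ / 2+ range has poor
inter-observer agreement, and *ERBB2* mRNA alone barely beats chance for
the low-vs-others call (an ordinal marker ranks 3+ tumors above low ones).
`her2lowsig` implements an observer-independent transcriptomic
alternative, for computational biologists and biostatisticians working
with annotated bulk expression cohorts.

## Method

For each HER2 IHC category K ∈ {0, 1+, 2+, 3+, low = 1+∪2+}, a one-vs-rest
screen keeps genes with |log2FC| > 1 (difference of log2 group means) and
tests the survivors with the two-sided Wilcoxon rank-sum test, Bonferroni-
adjusted within the contrast (significance at adjusted p < 0.05). A
sign-aware Venn step assigns significant genes to category-specific cells
(significance elsewhere with the opposite, rest-dilution-consistent sign
does not disqualify). The 1+/2+/low-specific genes, merged over discovery
cohorts, form the signature: with **w** the unit-norm leading eigenvector
of their Pearson correlation matrix **R** on the fit cohort
(R = (1/(n−1)) ZᵀZ, Z the per-gene standardized expression),

    score_i = s · Σ_g w_g z_gi ,

the sign s chosen so HER2-low samples score above HER2-zero samples.
Evaluation: Kruskal–Wallis across IHC categories with post hoc rank-sum
pairs (low vs 0, low vs 3+), ROC AUC for low-vs-others as Mann–Whitney
concordance with a DeLong 95% CI, a Youden-index cutoff, the full-order
partial-correlation network of the signature genes (r_p(i,j) =
−Ω_ij/√(Ω_ii Ω_jj), Ω = R⁻¹, edges at |r_p| > 0.30), and the same-label
AUC of single-gene *ERBB2* as a benchmark. A multi-cohort synthetic
generator with planted category-specific genes and a latent bell-shaped
"HER2-low factor" makes the whole pipeline testable end to end; see the
methods vignette (`vignettes/her2low-signature-methods.Rmd`).

## Worked example

```r
library(her2lowsig)

syn <- generate_cohorts(default_synthetic_config(seed = 7))
syn
#> SyntheticCohorts: 3 cohort(s), 304 samples, 1021 genes (20 planted)

cfg <- pipeline_config(discovery    = syn$datasets[c("INT1", "INT2")],
                       confirmatory = syn$datasets["INT3"], seed = 7)
res <- run_pipeline(cfg)

res$model
#> SignatureModel: 20 genes, PC1 explains 75.0% (fit on INT1)
#> top |weights|: PLLOW_001=0.239, PL1P_011=0.236, PL1P_004=0.235, ...

e <- res$evaluation$INT1
e$kw$p                      # 5.33e-13  (scores differ across IHC categories)
e$posthoc
#>     low_vs_zero low_vs_positive
#>    4.700987e-11    2.920423e-08
e$roc_low_vs_others
#> AUC = 0.908 (95% CI 0.859-0.957; 74 pos / 51 neg)
e$benchmark$benchmark        # single ERBB2-like gene, same labels
#> AUC = 0.561 (95% CI 0.438-0.685; 74 pos / 51 neg)

e$score_summary
#>   category  n   min      q1 median    q3  max
#> 1        0 33 -8.56 -5.1121  -3.50 -1.09 2.46
#> 2       1+ 62 -5.07  0.0797   2.73  4.17 7.77
#> 3       2+ 12 -3.05  0.3354   1.23  2.38 7.83
#> 4       3+ 18 -7.58 -4.8954  -2.99 -1.20 1.31
```

Reading the numbers: the 20 recovered genes form one coherent PC1 axis
(75% of the correlation-matrix variance). Scores are **bell-shaped** —
high medians in 1+ (2.73) and 2+ (1.23), low in 0 (−3.50) and 3+ (−2.99)
— so the signature separates HER2-low from *both* ends of the IHC scale
(post hoc p ≈ 5e−11 and 3e−8), and its low-vs-others AUC (0.91) far
exceeds the ordinal single-gene benchmark (0.56), whose confidence
interval straddles 0.5. With `output_dir` set, `run_pipeline()` also
writes `model.json`, per-cohort score TSVs, `report.json` (deterministic)
and a human-readable `report.md`.

The bundled development-population composition is available for cohort
arithmetic:

```r
cohort_summary(reference_cohort_annotations())
#> CohortSummary: 304 samples in 3 cohort(s)
#> HER2 groups: zero 110 (36%), low 162 (53%), positive 32 (11%)
```

## Command line

```sh
Rscript -e 'her2lowsig::cli_main()' simulate --config sim.json --out data/
Rscript -e 'her2lowsig::cli_main()' run-all  --config cfg.json --out out/
```
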