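---
title: "Methods: building and evaluating a HER2-low expression signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating a HER2-low expression signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2lowsig)
```

## The problem

HER2-low breast cancer — immunohistochemistry (IHC) 1+, or 2+ without
ERBB2 amplification at in-situ hybridization — has become a treatable
entity with antibody–drug conjugates, but the IHC read in exactly that
range (0 vs 1+ vs 2+) has poor inter-observer agreement. ERBB2 mRNA alone
does not rescue the call: an ordinal marker ranks 3+ tumors above low
ones, so its concordance for *low vs everything else* hovers near chance.
`her2lowsig` implements a transcriptomic alternative: find genes whose
expression is specific to individual IHC categories, combine them into a
single principal-component score, and evaluate whether that score
separates HER2-low tumors from both ends of the IHC scale.

## The procedure

Given one or more discovery cohorts of log2 expression with per-sample
IHC annotations, the pipeline (`run_pipeline()`) executes:

1. **One-vs-rest screening** (`select_contrast_degs()`). Five contrasts —
   0, 1+, 2+, 3+ each against the rest, and the low union (1+ and 2+)
   against the rest. Stage 1 keeps genes with |log2 fold change| > 1
   (difference of group means on the log2 scale); stage 2 applies the
   two-sided Wilcoxon rank-sum test to the surviving genes only, with
   Bonferroni adjustment over the survivors of that contrast and
   significance at adjusted p < 0.05. The per-contrast family keeps
   contrasts with very different survivor counts comparable; a global
   family is available via `family = "all"`.
2. **Venn attribution** (`venn_specific_genes()`). Significant genes are
   assigned to exactly-one-contrast "specific" cells. See below for why
   the default attribution is sign-aware.
3. **Merge** (`merge_discovery()`). The 1+, 2+ and low cells are pooled
   across discovery cohorts; a gene claimed by different categories in
   different cohorts is a hard error by default. The 0- and 3+-specific
   cells are reported but do not feed the signature: the goal is a score
   that is *high* in the low range, and the 1+/2+/low cells are the ones
   that carry that contrast.
4. **Signature fit** (`fit_signature()`). On the fit cohort (by default
   the first discovery cohort with all four IHC categories), the Pearson
   correlation matrix of the selected genes is eigendecomposed; the
   unit-norm leading eigenvector gives the gene weights, and
   lambda_1 / sum(lambda) the explained-variance share. A PCA eigenvector
   has no intrinsic sign, so orientation is fixed by requiring
   mean(score | HER2-low) > mean(score | HER2-zero) on the fit cohort. A
   relative gap below `eigen_gap_tol` between the top two eigenvalues is
   an error: PC1 would not be identifiable.
5. **Scoring** (`score_samples()`). score = orientation * sum_g w_g z_g
   over standardized expression. The default transfer rule re-standardizes
   per scored dataset, which is exactly invariant to per-gene affine
   platform effects — the property needed to score cohorts profiled on
   different platforms. Reusing training means/SDs (`"train-params"`) is
   supported but is platform-sensitive by construction.
6. **Evaluation** (`kruskal_wallis()`, `pairwise_posthoc()`, `roc_auc()`,
   `youden_cutoff()`, `partial_correlation_matrix()`,
   `compare_signature_vs_gene()`). Kruskal–Wallis (tie-corrected H,
   chi-square p) across IHC categories; post hoc two-sided rank-sum tests
   for low-vs-zero and low-vs-positive, unadjusted by default (a
   Bonferroni switch over the requested pairs exists); ROC AUC for low vs
   others as the Mann–Whitney concordance with ties counting 1/2, with a
   DeLong structural-components 95% CI; a Youden-maximizing cutoff; the
   full-order partial-correlation network of the signature genes from the
   precision matrix, reporting edges with |r_p| > 0.30; and the same-label
   AUC of a single benchmark gene (ERBB2) for comparison.

## Why the Venn attribution is sign-aware

In a one-vs-rest scheme the contrasts are not independent: the "rest" of
every other contrast contains the focal samples. A gene up-shifted by
delta only in category K with focal fraction p appears in the K' contrast
with fold change −delta·p/(1−p_K') — with four equal categories a low
(1+/2+) gene has fold change exactly −delta·(2/3) in the 0-vs-others
contrast and is *always* significantly "down in 0" once delta clears the
screen. Plain five-way exclusivity would therefore discard precisely the
cleanest category-specific genes. The default attribution uses the sign
pattern instead:

* significance in another contrast with the *opposite* (dilution-
  consistent) sign corroborates specificity and does not disqualify;
* a gene significant in 1+ and 2+ with the *same* sign, and in the low
  union, shows the bell pattern of a genuine HER2-low gene and is
  assigned to the low cell;
* a gene with several surviving candidacies is assigned to the contrast
  with the largest absolute fold change (deterministic tie-break);
* anything else significant lands in the reported overlap.

`mode = "exclusive"` provides the plain set-arithmetic Venn for
comparison; on patterns without dilution leakage the two modes agree.

## The synthetic world

`generate_cohorts()` emulates the structure the method was developed on,
so every stage is testable without patient-level data:

* **Cohorts and categories.** `default_synthetic_config()` uses three
  cohorts with IHC category counts 33/62/12/18, 52/32/0/0 and
  25/26/30/14 (n = 304 in total; the second cohort lacks 2+ and 3+,
  exercising the contrast-skipping path).
* **Expression model.** Background gene g in cohort c:
  mu_g + o_gc + eps, with mu_g ~ N(7, 1), per-gene platform offsets
  o_gc ~ N(0, 0.25^2) and eps ~ N(0, sigma^2), sigma = 0.5. Gaussian
  noise on the log2 scale is adequate because the downstream tests are
  rank-based; additive planted shifts make "planted log2FC = delta" exact
  in expectation.
* **Planted genes.** 11 genes shifted by delta in 1+, 8 in 2+, 1 in the
  low union; delta defaults to 1.5 (a DEG that clears a |log2FC| > 1
  screen with moderate margin; the suite's recovery experiments use
  delta = 2).
* **Latent HER2-low factor.** Every planted gene additionally loads
  (lambda = 0.8) on a per-sample factor h ~ N(m, 1) with m = 1 in 1+/2+
  and m = 0 in 0/3+. This factor is the modeled analogue of the shared
  biology (largely hormone-receptor–linked co-regulation) that makes a
  single PC1 axis meaningful in real data. Two failed alternatives are
  instructive and motivated the design: with no shared factor the 1+ and
  2+ gene blocks are *negatively* correlated through their category
  indicators (cov −delta²·p1·p2), PC1 captures only the larger block,
  and the score is not bell-shaped in a sizable minority of simulations;
  with a zero-mean shared factor the coupling is marginal and the
  factor's shared noise can sink an entire small-category block below
  the fold-change screen at once. With the bell-mean factor the ordering
  median(1+) > median(0) and median(2+) > median(3+) holds in 60/60
  simulated worlds across three disjoint seed blocks.
* **Benchmark gene.** An `ERBB2` gene with nondecreasing category means
  (8, 8.5, 9, 11.5): ordinal in IHC, hence nearly uninformative for
  low-vs-others (its concordance gains against 0 are cancelled by losses
  against 3+), reproducing the qualitative AUC gap the signature is
  meant to beat.
* **Confounding and truth.** HR-positive probability per category
  (0.28, 0.74, 0.74, 0.63) mirrors the development population's
  cross-tabulation; planted-gene identities and effects are returned as
  a ground-truth sidecar, never inside the expression files.

What a green simulation does **not** establish: the generator has no
probe-level artifacts, no count noise, no missing values, no correlated
background modules, and its HR status influences nothing but the
annotation. Recovery and bell-shape results certify the pipeline's
logic, not clinical performance.

## Numerical choices and degenerate inputs

* Wilcoxon p-values are exact (no ties, smaller group <= 8) or
  normal-approximated with tie and continuity corrections; two groups of
  identical constants return p = 1 with a warning.
* Bonferroni requires the family size to be at least the number of tests.
* Youden candidates are midpoints between adjacent distinct scores plus
  ±Inf ("positive" means score > cutoff); ties in J resolve to the
  smallest cutoff, maximizing sensitivity.
* A degenerate AUC of 0 or 1 yields a clipped, zero-width DeLong interval
  with a warning rather than an error.
* Partial correlations require more samples than genes + 1 and an
  invertible correlation matrix; failures name the remedy (reduce the
  gene set).
* Missing expression values are rejected at load with their location —
  imputation inside a scoring pipeline would silently shift scores.
* Percentages in summary tables round half-up to integers, matching
  clinical-table convention.
* IHC 2+ with unknown ISH status maps to HER2-low (the convention of the
  development population's published tables); `classify_her2_group()`
  exposes the alternative.
* Report JSON is written with 17-significant-digit numbers and no
  timestamps, so reruns with the same seed and config are byte-identical.

## Known limitations

* The sign-aware attribution can misassign a genuine low-union gene to a
  single category in the rare event that its dilution image reaches
  significance in exactly one of 1+/2+.
* With fewer samples than signature genes the PCA fit warns but
  proceeds; weights are then unstable and transfer poorly.
* The bundled development-population annotation table
  (`reference_cohort_annotations()`) is faithful only in its published
  margins and HER2-group cross-tabulations; unpublished joint cells are
  filled deterministically and carry no information.
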