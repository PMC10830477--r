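# Statistical evaluation of the signature: k-group comparison, post hoc
# pairwise tests, ROC/AUC with DeLong confidence intervals, Youden cutoff,
# full-order partial-correlation network, single-gene benchmark.

#' Kruskal-Wallis comparison of scores across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on (k - 1) degrees of
#' freedom. Empty groups are dropped with a warning; if every observation is
#' identical the test is degenerate (H = 0, p = 1, warning).
#'
#' @param scores Numeric vector (or `SignatureScores`, whose `score` column
#'   is used).
#' @param groups Group labels, same length as the scores.
#' @return List with `statistic`, `df`, `p`, `groups_used`.
#' @export
kruskal_wallis <- function(scores, groups) {
  x <- if (inherits(scores, "SignatureScores")) scores$score else scores
  stopifnot(length(x) == length(groups))
  groups <- as.character(groups)
  keep <- !is.na(x) & !is.na(groups)
  x <- x[keep]; groups <- groups[keep]
  tab <- table(groups)
  empty <- names(tab)[tab == 0]
  if (length(empty)) warning("dropping empty group(s): ",
                             paste(empty, collapse = ", "))
  if (length(unique(groups)) < 2)
    stop("Kruskal-Wallis needs at least 2 non-empty groups")
  if (length(unique(x)) == 1L) {
    warning("kruskal_wallis: all observations identical; H = 0, p = 1")
    return(list(statistic = 0, df = length(unique(groups)) - 1L, p = 1,
                groups_used = sort(unique(groups))))
  }
  kt <- stats::kruskal.test(x, factor(groups))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, groups_used = sort(unique(groups)))
}

#' Post hoc pairwise rank-sum comparisons
#'
#' Two-sided [rank_sum_test()] p-value per requested group pair, unadjusted
#' by default (`adjust = "bonferroni"` multiplies by the number of requested
#' pairs). Pairs with an empty side are reported as `NA` with a warning.
#'
#' @param scores Numeric vector or `SignatureScores`.
#' @param groups Group labels, same length.
#' @param pairs List of length-2 character vectors; default compares
#'   HER2-low against zero and against positive.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Named numeric vector of p-values (`"a_vs_b"` names).
#' @export
pairwise_posthoc <- function(scores, groups,
                             pairs = list(c("low", "zero"),
                                          c("low", "positive")),
                             adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  x <- if (inherits(scores, "SignatureScores")) scores$score else scores
  stopifnot(length(x) == length(groups))
  groups <- as.character(groups)
  if (!length(pairs)) return(stats::setNames(numeric(), character()))
  p <- vapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    a <- x[groups == pr[1]]; b <- x[groups == pr[2]]
    if (!length(a) || !length(b)) {
      warning(sprintf("pair %s vs %s has an empty group; p = NA",
                      pr[1], pr[2]))
      return(NA_real_)
    }
    rank_sum_test(a, b)
  }, 0)
  names(p) <- vapply(pairs, function(pr) paste(pr, collapse = "_vs_"), "")
  if (adjust == "bonferroni") p <- pmin(1, p * length(p))
  p
}

#' ROC AUC with DeLong 95% confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties count 1/2): the
#' probability that a random positive scores above a random negative. The
#' confidence interval uses DeLong's structural-components variance with a
#' normal approximation, clipped to \[0, 1\]; a degenerate AUC of exactly 0
#' or 1 yields a zero-width interval with a warning.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1, or two-level factor) vector; `TRUE` = the
#'   positive class.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `ROCResult`: `auc`, `ci_low`, `ci_high`,
#'   `se`, `n_pos`, `n_neg`, `conf_level`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels]; neg <- scores[!labels]
  if (!length(pos) || !length(neg))
    stop("both classes must be present to compute an AUC")
  m <- length(pos); n <- length(neg)
  # placement values: V10_i = P(neg < pos_i) + P(neg == pos_i)/2, and dually
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(auc - z * se, auc + z * se)
  if (auc %in% c(0, 1) || se == 0)
    warning("degenerate AUC or zero DeLong variance; confidence interval clipped")
  ci <- pmin(1, pmax(0, ci))
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2], se = se,
                 n_pos = m, n_neg = n, conf_level = conf_level),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%d%% CI %.3f-%.3f; %d pos / %d neg)\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @keywords internal
#' @noRd
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  f <- factor(labels)
  if (nlevels(f) == 1) return(rep(FALSE, length(labels)))
  if (nlevels(f) != 2)
    stop("labels must be binary (logical, 0/1, or two-level)")
  f == levels(f)[2]
}

#' Youden-index cutoff for a score
#'
#' Evaluates J = sensitivity + specificity - 1 at every candidate cutoff
#' (midpoints between adjacent distinct scores, plus -Inf and +Inf; a sample
#' is called positive when its score exceeds the cutoff) and returns the
#' cutoff maximizing J. Ties on J are broken toward the smallest cutoff,
#' which maximizes sensitivity.
#'
#' @inheritParams roc_auc
#' @return An object of class `CutoffResult`: `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present to pick a cutoff")
  s <- sort(unique(scores))
  candidates <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  m <- sum(labels); n <- sum(!labels)
  eval_j <- vapply(candidates, function(cut) {
    sens <- sum(scores[labels] > cut) / m
    spec <- sum(scores[!labels] <= cut) / n
    c(sens, spec, sens + spec - 1)
  }, numeric(3))
  best <- which.max(eval_j[3, ])  # which.max returns the first (smallest) tie
  if (length(s) == 1L)
    warning("all scores identical; Youden index is degenerate (J = 0)")
  structure(list(cutoff = candidates[best],
                 sensitivity = eval_j[1, best],
                 specificity = eval_j[2, best],
                 youden_j = eval_j[3, best]), class = "CutoffResult")
}

#' Full-order partial-correlation network of the signature genes
#'
#' The partial correlation of two genes given all other genes is computed
#' from the precision matrix (inverse of the genes' Pearson correlation
#' matrix): `r_p(i,j) = -Omega_ij / sqrt(Omega_ii * Omega_jj)`. Edges with
#' `|r_p|` above the reporting threshold are listed.
#'
#' @param dataset An [expression_dataset()] or a samples x genes numeric
#'   matrix.
#' @param genes Genes to include (>= 2).
#' @param edge_threshold Absolute partial-correlation reporting bar
#'   (default 0.30).
#' @return An object of class `PartialCorrelationNetwork`: `genes`, `r_p`
#'   (symmetric, unit diagonal), `edges` (`data.frame` gene1/gene2/r_p sorted
#'   by |r_p|), `edge_threshold`.
#' @export
partial_correlation_matrix <- function(dataset, genes = NULL,
                                       edge_threshold = 0.30) {
  if (inherits(dataset, "ExpressionDataset")) {
    genes <- genes %||% dataset$genes
    x <- t(dataset$matrix[genes, , drop = FALSE])
  } else {
    x <- as.matrix(dataset)
    if (!is.null(genes)) x <- x[, genes, drop = FALSE]
    genes <- colnames(x)
  }
  p <- ncol(x)
  stopifnot(p >= 2)
  if (nrow(x) <= p + 1)
    stop(sprintf("need more samples (%d) than genes + 1 (%d) for a stable precision matrix",
                 nrow(x), p + 1))
  cmat <- stats::cor(x)
  if (any(!is.finite(cmat))) stop("correlation matrix not computable")
  omega <- tryCatch(solve(cmat), error = function(e)
    stop("singular correlation matrix; reduce the gene set (", conditionMessage(e), ")"))
  d <- sqrt(diag(omega))
  rp <- -omega / tcrossprod(d)
  diag(rp) <- 1
  rp <- (rp + t(rp)) / 2
  dimnames(rp) <- list(genes, genes)
  idx <- which(upper.tri(rp) & abs(rp) > edge_threshold, arr.ind = TRUE)
  edges <- data.frame(gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
                      r_p = rp[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r_p)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genes = genes, r_p = rp, edges = edges,
                 edge_threshold = edge_threshold),
            class = "PartialCorrelationNetwork")
}

#' @export
print.PartialCorrelationNetwork <- function(x, ...) {
  cat(sprintf("PartialCorrelationNetwork: %d genes, %d edge(s) with |r_p| > %.2f\n",
              length(x$genes), nrow(x$edges), x$edge_threshold))
  if (nrow(x$edges))
    print(utils::head(transform(x$edges, r_p = round(r_p, 2)), 10))
  invisible(x)
}

#' Benchmark the signature against a single gene's expression
#'
#' Computes the ROC AUC (with DeLong CI) of the signature score and of the
#' raw expression of a benchmark gene (typically the ERBB2 transcript
#' itself) against the same binary HER2-low-vs-others labels.
#'
#' @param model A fitted [fit_signature()] model.
#' @param dataset Dataset to evaluate on.
#' @param benchmark_gene Gene symbol present in `dataset` (default
#'   `"ERBB2"`).
#' @param positive HER2 group(s) forming the positive class (default
#'   `"low"`).
#' @param standardization_mode Passed to [score_samples()].
#' @return List with `signature` and `benchmark` (`ROCResult`s) and
#'   `auc_difference` (signature minus benchmark).
#' @export
compare_signature_vs_gene <- function(model, dataset,
                                      benchmark_gene = "ERBB2",
                                      positive = "low",
                                      standardization_mode = "per-dataset") {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!benchmark_gene %in% dataset$genes)
    stop("benchmark gene '", benchmark_gene, "' absent from dataset")
  grp <- classify_her2_group(dataset$samples$ihc_score,
                             dataset$samples$ish_amplified)
  labels <- grp %in% positive
  sig <- score_samples(model, dataset,
                       standardization_mode = standardization_mode)
  roc_sig <- roc_auc(sig$score, labels)
  roc_gene <- roc_auc(dataset$matrix[benchmark_gene, ], labels)
  list(signature = roc_sig, benchmark = roc_gene,
       auc_difference = roc_sig$auc - roc_gene$auc)
}

#' Per-category five-number score summaries
#'
#' Box-plot-ready table (one row per IHC category: n, median, quartiles,
#' extremes) of signature scores, mirroring the distribution-by-category
#' figures of signature evaluations.
#'
#' @param scores `SignatureScores` or numeric vector.
#' @param categories IHC category (or any group) label per sample.
#' @return `data.frame` with columns `category`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
score_summary_by_category <- function(scores, categories) {
  x <- if (inherits(scores, "SignatureScores")) scores$score else scores
  stopifnot(length(x) == length(categories))
  cats <- unique(as.character(categories))
  cats <- cats[order(match(cats, c(IHC_LEVELS, HER2_GROUPS)), cats)]
  out <- do.call(rbind, lapply(cats, function(k) {
    v <- x[categories == k]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(category = k, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
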