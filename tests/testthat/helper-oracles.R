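# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately brute-force and share no code with the package.

# Exact two-sided rank-sum p-value by full enumeration of all C(n1+n2, n1)
# assignments of the pooled ranks to group x. No-ties inputs only.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
enum_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Best achievable Youden index by exhaustive scan of "score > t" rules.
enum_max_youden <- function(scores, labels) {
  cand <- c(-Inf, sort(unique(scores)))
  max(vapply(cand, function(t)
    mean(scores[labels] > t) - mean(scores[!labels] > t), 0))
}

# Partial correlation of columns i and j given all others, by correlating
# the residuals of two regressions on the conditioning set.
resid_partial_cor <- function(x, i, j) {
  others <- setdiff(seq_len(ncol(x)), c(i, j))
  if (!length(others)) return(stats::cor(x[, i], x[, j]))
  ri <- stats::lm.fit(cbind(1, x[, others, drop = FALSE]), x[, i])$residuals
  rj <- stats::lm.fit(cbind(1, x[, others, drop = FALSE]), x[, j])$residuals
  stats::cor(ri, rj)
}

# Minimal ExpressionDataset from a bare matrix and IHC labels.
make_ds <- function(mat, ihc, cohort = "T1", hr = "unknown",
                    ish = "unknown") {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
  ann <- data.frame(sample_id = colnames(mat), cohort = cohort,
                    ihc_score = ihc, ish_amplified = ish, hr_status = hr,
                    stringsAsFactors = FALSE)
  expression_dataset(mat, ann)
}

# Small-but-structured random dataset: planted 1+/2+/low genes over a
# single balanced cohort; cheap enough for per-test generation.
small_synthetic <- function(seed = 1, n_per_cat = 15, n_bg = 200,
                            delta = 2, sd = 0.5, ...) {
  cfg <- synthetic_config(matrix(rep(n_per_cat, 4), 1,
                                 dimnames = list("T1", NULL)),
                          n_background_genes = n_bg,
                          planted_sets = list("1+" = list(n = 4, delta = delta),
                                              "2+" = list(n = 3, delta = delta),
                                              "low" = list(n = 2, delta = delta)),
                          noise_sd = sd, cohort_offset_sd = 0, seed = seed, ...)
  generate_cohorts(cfg)
}
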