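test_that("kruskal_wallis matches hand computation and handles edge cases", {
  r <- kruskal_wallis(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(r$statistic, 2)          # H = 12/(3*4) * sum(n_i (Rbar_i - 2)^2)
  expect_equal(r$df, 2)
  expect_warning(r0 <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3)),
                 "identical")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "at least 2")
})

test_that("two-group KW agrees with the rank-sum test decision-wise", {
  set.seed(5)
  agree <- 0; reps <- 600
  for (i in seq_len(reps)) {
    x <- rnorm(50); y <- rnorm(50)
    p_kw <- kruskal_wallis(c(x, y), rep(c("a", "b"), each = 50))$p
    p_w <- rank_sum_test(x, y)
    agree <- agree + ((p_kw < 0.05) == (p_w < 0.05))
  }
  expect_gte(agree / reps, 0.99)
})

test_that("pairwise_posthoc tests the requested pairs only", {
  sc <- c(1, 2, 3, 4, 5, 6)
  g <- c("zero", "zero", "low", "low", "positive", "positive")
  p <- pairwise_posthoc(sc, g)
  expect_named(p, c("low_vs_zero", "low_vs_positive"))
  p_same <- pairwise_posthoc(c(1, 2, 1, 2), c("low", "low", "zero", "zero"),
                             pairs = list(c("low", "zero")))
  expect_equal(unname(p_same), 1)
  expect_equal(length(pairwise_posthoc(sc, g, pairs = list())), 0)
  expect_warning(p_na <- pairwise_posthoc(sc, g, pairs = list(c("low", "nope"))),
                 "empty group")
  expect_true(is.na(p_na))
  p_adj <- pairwise_posthoc(sc, g, adjust = "bonferroni")
  expect_equal(unname(p_adj), pmin(1, unname(p) * 2))
})

test_that("roc_auc equals the concordant-pair oracle, with and without ties", {
  r <- roc_auc(c(2, 3, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  set.seed(6)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(1:8, n, replace = TRUE) / 2   # plenty of ties
    expect_equal(roc_auc(scores, labels)$auc, enum_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_warning(rp <- roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)),
                 "degenerate")
  expect_equal(rp$auc, 1)
  expect_true(rp$ci_low >= 0 && rp$ci_high <= 1)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("DeLong intervals cover the true AUC at the nominal rate", {
  set.seed(7)
  mu <- 1; true_auc <- pnorm(mu / sqrt(2))
  reps <- 2000; covered <- 0
  for (i in seq_len(reps)) {
    scores <- c(rnorm(100, mu), rnorm(100))
    labels <- rep(c(TRUE, FALSE), each = 100)
    r <- roc_auc(scores, labels)
    covered <- covered + (r$ci_low <= true_auc && true_auc <= r$ci_high)
  }
  expect_gte(covered / reps, 0.92)
  expect_lte(covered / reps, 0.975)
})

test_that("youden_cutoff scans candidates and breaks ties low", {
  r <- youden_cutoff(c(2, 3, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$cutoff, 1.5)           # two J = 0.5 candidates; lower wins
  expect_equal(r$youden_j, 0.5)
  expect_equal(r$sensitivity + r$specificity - 1, r$youden_j)
  # perfect separation: J = 1 at the gap midpoint
  rp <- youden_cutoff(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rp$youden_j, 1)
  expect_equal(rp$cutoff, 6)
  expect_warning(rd <- youden_cutoff(rep(3, 4), c(TRUE, TRUE, FALSE, FALSE)),
                 "degenerate")
  expect_equal(rd$youden_j, 0)
  # achieved J equals the exhaustive-scan oracle
  set.seed(8)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(1:6, n, replace = TRUE)
    expect_equal(youden_cutoff(scores, labels)$youden_j,
                 enum_max_youden(scores, labels), tolerance = 1e-12)
  }
})

test_that("partial correlations match definition and the residual oracle", {
  set.seed(9)
  # two genes: partial correlation reduces to the Pearson correlation
  x2 <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  net2 <- partial_correlation_matrix(x2)
  expect_equal(net2$r_p["a", "b"], cor(x2[, 1], x2[, 2]), tolerance = 1e-12)
  # residual-regression oracle on correlated data
  for (rep in 1:5) {
    p <- sample(3:6, 1); n <- 80
    z <- rnorm(n)
    x <- sapply(seq_len(p), function(j) 0.6 * z + rnorm(n))
    colnames(x) <- paste0("g", seq_len(p))
    net <- partial_correlation_matrix(x)
    expect_true(isSymmetric(net$r_p))
    expect_equal(unname(diag(net$r_p)), rep(1, p))
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      expect_equal(net$r_p[i, j], resid_partial_cor(x, i, j),
                   tolerance = 1e-10)
  }
  # independent genes: off-diagonal r_p vanishes with n
  xi <- matrix(rnorm(4 * 2000), 2000, 4, dimnames = list(NULL, paste0("g", 1:4)))
  neti <- partial_correlation_matrix(xi)
  expect_true(all(abs(neti$r_p[upper.tri(neti$r_p)]) < 3 / sqrt(2000)))
  expect_equal(nrow(neti$edges), 0)
  # guards
  xs <- cbind(x2, c = x2[, 1])
  expect_error(partial_correlation_matrix(xs), "singular|reduce")
  expect_error(partial_correlation_matrix(x2[1:3, ]), "samples")
})

test_that("edge listing respects the reporting threshold", {
  set.seed(11)
  z <- rnorm(150)
  x <- cbind(a = z + rnorm(150, sd = 0.6), b = z + rnorm(150, sd = 0.6),
             c = rnorm(150))
  net <- partial_correlation_matrix(x, edge_threshold = 0.30)
  expect_true(all(abs(net$edges$r_p) > 0.30))
  expect_true(any(net$edges$gene1 == "a" & net$edges$gene2 == "b"))
})

test_that("signature-vs-gene comparison uses one label set for both AUCs", {
  syn <- small_synthetic(seed = 12, n_per_cat = 20)
  d <- syn$datasets[[1]]
  genes <- syn$ground_truth$gene[syn$ground_truth$planted_contrast != "ordinal"]
  model <- fit_signature(d, genes)
  cmp <- compare_signature_vs_gene(model, d)
  expect_s3_class(cmp$signature, "ROCResult")
  expect_equal(cmp$auc_difference, cmp$signature$auc - cmp$benchmark$auc)
  expect_error(compare_signature_vs_gene(model, d, benchmark_gene = "NOPE"),
               "absent")
  # a benchmark gene that IS the score must tie the signature exactly
  sc <- score_samples(model, d)
  mat <- rbind(d$matrix, SCOREGENE = sc$score)
  d2 <- expression_dataset(mat, d$samples)
  cmp2 <- compare_signature_vs_gene(model, d2, benchmark_gene = "SCOREGENE")
  expect_equal(cmp2$auc_difference, 0, tolerance = 1e-12)
})

test_that("score_summary_by_category yields ordered five-number rows", {
  s <- score_summary_by_category(c(1, 2, 3, 4, 5, 6),
                                 c("1+", "0", "1+", "3+", "0", "2+"))
  expect_equal(s$category, c("0", "1+", "2+", "3+"))
  expect_equal(s$n, c(2, 2, 1, 1))
  expect_equal(s$median[1], 3.5)
})
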