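test_that("standardize_genes fits, applies, and validates", {
  syn <- small_synthetic(seed = 1, n_per_cat = 10, n_bg = 20)
  d <- syn$datasets[[1]]
  genes <- d$genes[1:5]
  std <- standardize_genes(d, genes, mode = "fit")
  expect_true(all(abs(rowMeans(std$z)) < 1e-12))
  expect_true(all(abs(apply(std$z, 1, sd) - 1) < 1e-12))
  # location invariance: shifting every value leaves z unchanged
  d_shift <- expression_dataset(d$matrix + 5, d$samples)
  expect_equal(standardize_genes(d_shift, genes, mode = "fit")$z, std$z)
  # apply mode uses the supplied parameters: (4 - 2) / 2 = 1
  one <- make_ds(matrix(4, 1, 1, dimnames = list("g", "s1")), "0")
  z <- standardize_genes(one, "g", mode = "apply",
                         params = list(mean = c(g = 2), sd = c(g = 2)))$z
  expect_equal(unname(z[1, 1]), 1)
  expect_error(standardize_genes(d, c("g001", "nope")), "nope")
  const <- make_ds(matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE,
                          dimnames = list(c("flat", "ok"), paste0("s", 1:3))),
                   c("0", "1+", "1+"))
  expect_error(standardize_genes(const, c("flat", "ok")), "flat")
})

test_that("fit_signature matches closed forms on two genes", {
  set.seed(10)
  base <- rnorm(40)
  # perfectly correlated pair: affine copies, r = 1 exactly
  mat <- rbind(g1 = base, g2 = 2 * base + 3)
  d <- make_ds(mat, rep(c("0", "1+"), each = 20))
  m <- suppressWarnings(fit_signature(d, c("g1", "g2")))
  expect_equal(abs(unname(m$weights)), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(m$explained_share, 1, tolerance = 1e-12)
  # general pair: eigenvalues 1 +/- r, explained share (1 + |r|) / 2
  mat2 <- rbind(g1 = base, g2 = 0.6 * base + rnorm(40, sd = 0.8))
  r <- abs(cor(mat2["g1", ], mat2["g2", ]))
  d2 <- make_ds(mat2, rep(c("0", "1+"), each = 20))
  m2 <- fit_signature(d2, c("g1", "g2"))
  expect_equal(m2$explained_share, (1 + r) / 2, tolerance = 1e-12)
  # exactly orthogonal pair: tied eigenvalues are rejected
  m3 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  d3 <- make_ds(m3, c("0", "0", "1+", "1+"))
  expect_error(suppressWarnings(fit_signature(d3, c("g1", "g2"))), "tied")
})

test_that("independent genes drive the explained share towards 1/p", {
  set.seed(20)
  p <- 5; n <- 10000
  mat <- matrix(rnorm(p * n), p, n,
                dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  d <- make_ds(mat, rep(c("0", "1+"), length.out = n))
  m <- fit_signature(d, rownames(mat))
  # Marchenko-Pastur edge for the leading sample eigenvalue of identity:
  # lambda_1 <= (1 + sqrt(p/n))^2 up to fluctuation
  expect_gt(m$explained_share, 1 / p)
  expect_lt(m$explained_share, (1 + 3 * sqrt(p / n))^2 / p)
})

test_that("scores equal the eigenprojection oracle on the fitting data", {
  syn <- small_synthetic(seed = 30, n_per_cat = 25)
  d <- syn$datasets[[1]]
  genes <- syn$ground_truth$gene[syn$ground_truth$planted_contrast != "ordinal"]
  model <- fit_signature(d, genes)
  sc <- score_samples(model, d, standardization_mode = "per-dataset")
  # oracle: direct eigendecomposition + projection of standardized data
  z <- scale(t(d$matrix[genes, ]))
  eg <- eigen(cor(t(d$matrix[genes, ])), symmetric = TRUE)
  proj <- drop(z %*% eg$vectors[, 1])
  if (cor(proj, sc$score) < 0) proj <- -proj
  expect_equal(sc$score, unname(proj), tolerance = 1e-10)
  # orientation contract: mean score of low exceeds mean score of zero
  grp <- classify_her2_group(d$samples$ihc_score)
  expect_gt(mean(sc$score[grp == "low"]), mean(sc$score[grp == "zero"]))
})

test_that("per-dataset standardization makes scores platform-invariant", {
  syn <- small_synthetic(seed = 31, n_per_cat = 15)
  d <- syn$datasets[[1]]
  genes <- syn$ground_truth$gene[syn$ground_truth$planted_contrast != "ordinal"]
  model <- fit_signature(d, genes)
  a <- runif(length(d$genes), 0.5, 2)   # per-gene gain
  b <- rnorm(length(d$genes), 0, 3)     # per-gene offset
  d_shift <- expression_dataset(d$matrix * a + b, d$samples)
  s1 <- score_samples(model, d, "per-dataset")
  s2 <- score_samples(model, d_shift, "per-dataset")
  expect_equal(s2$score, s1$score, tolerance = 1e-10)
  # train-params mode is NOT invariant (by design)
  s3 <- score_samples(model, d_shift, "train-params")
  expect_false(isTRUE(all.equal(s3$score, s1$score, tolerance = 1e-4)))
  # a sample sitting at the training means scores zero
  at_mean <- matrix(model$train_mean, ncol = 1,
                    dimnames = list(model$genes, "s1"))
  d0 <- make_ds(at_mean, "0")
  s0 <- score_samples(model, d0, "train-params")
  expect_equal(s0$score, 0)
})

test_that("missing signature genes follow the declared policy", {
  syn <- small_synthetic(seed = 32, n_per_cat = 15)
  d <- syn$datasets[[1]]
  genes <- syn$ground_truth$gene[syn$ground_truth$planted_contrast != "ordinal"]
  model <- fit_signature(d, genes)
  keep <- setdiff(d$genes, genes[1])
  d_less <- expression_dataset(d$matrix[keep, ], d$samples)
  expect_error(score_samples(model, d_less), genes[1])
  expect_warning(
    expect_warning(s <- score_samples(model, d_less, missing_genes = "drop"),
                   "dropping"),
    "renormalized")
  expect_equal(nrow(s), nrow(d$samples))
})

test_that("model serialization round-trips bit-exactly", {
  syn <- small_synthetic(seed = 33, n_per_cat = 15)
  genes <- syn$ground_truth$gene[syn$ground_truth$planted_contrast != "ordinal"]
  model <- fit_signature(syn$datasets[[1]], genes)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(model, path)
  model2 <- read_signature_model(path)
  expect_identical(model2$weights, model$weights)
  expect_identical(model2$train_mean, model$train_mean)
  expect_identical(model2$train_sd, model$train_sd)
  expect_identical(model2$orientation, model$orientation)
  expect_identical(model2$explained_share, model$explained_share)
  expect_identical(model2$genes, model$genes)
})
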