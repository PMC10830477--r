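test_that("log2_fold_change is the difference of group means", {
  mat <- rbind(gA = c(3, 3, 1, 1),
               gB = c(2.5, 3.5, 3.0, 99),   # filler column, excluded below
               gC = c(5, 6, 5, 6))
  colnames(mat) <- paste0("s", 1:4)
  d <- make_ds(mat, c("1+", "1+", "0", "0"))
  ctr <- list(name = "1+", focal = c("s1", "s2"), rest = c("s3", "s4"))
  expect_equal(unname(log2_fold_change(d, ctr, "gA")), 2.0)
  mat2 <- rbind(g = c(2.5, 3.5, 3.0, 1.0, 2.0))
  colnames(mat2) <- paste0("s", 1:5)
  d2 <- make_ds(mat2, c("1+", "1+", "1+", "0", "0"))
  ctr2 <- list(name = "1+", focal = paste0("s", 1:3), rest = paste0("s", 4:5))
  expect_equal(unname(log2_fold_change(d2, ctr2, "g")), 1.5)
  # identical distributions give zero
  expect_equal(unname(log2_fold_change(
    d, list(name = "x", focal = c("s1", "s2"), rest = c("s3", "s4")), "gC")), 0)
  expect_error(log2_fold_change(d, list(name = "e", focal = character(),
                                        rest = colnames(mat)), "gA"),
               "empty group")
})

test_that("rank_sum_test matches exact enumeration and handles degeneracy", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(rank_sum_test(c(5, 1, 3), c(5, 1, 3)), 1)
  expect_warning(p <- rank_sum_test(rep(2, 4), rep(2, 3)), "identical")
  expect_equal(p, 1)
  set.seed(42)
  for (i in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(100, n1 + n2)            # distinct values, no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(rank_sum_test(x, y), enum_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("screening p-values are rank-invariant, fold changes are not", {
  syn <- small_synthetic(seed = 2, n_per_cat = 10, n_bg = 30)
  d <- syn$datasets[[1]]
  ctr <- her2_contrast(d, "low")
  g <- "PL1P_001"
  x <- d$matrix[g, ctr$focal]; y <- d$matrix[g, ctr$rest]
  expect_equal(rank_sum_test(exp(x), exp(y)), rank_sum_test(x, y))
  d_mono <- expression_dataset(2^d$matrix / 50, d$samples)  # monotone, nonlinear
  expect_false(isTRUE(all.equal(log2_fold_change(d_mono, ctr, g),
                                log2_fold_change(d, ctr, g))))
})

test_that("bonferroni_adjust multiplies, caps, and validates the family", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.3, 5), 1)
  expect_equal(bonferroni_adjust(c(0.001, 0.02, 0.04), 3),
               c(0.003, 0.06, 0.12))
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "smaller than")
})

test_that("select_contrast_degs honours the two-stage contract", {
  syn <- small_synthetic(seed = 8, n_per_cat = 30)
  d <- syn$datasets[[1]]
  ctr <- her2_contrast(d, "1+")
  res <- select_contrast_degs(d, ctr)
  expect_true(all(res$p_adj >= res$p_raw, na.rm = TRUE))
  expect_true(all(res$p_adj <= 1, na.rm = TRUE))
  expect_true(all(res$passed_fc == (abs(res$log2fc) > 1)))
  expect_true(all(res$passed_fc[res$passed_sig]))      # sig implies flagged
  expect_true(all(is.na(res$p_raw[!res$passed_fc])))   # tests only flagged genes
  planted <- syn$ground_truth$gene[syn$ground_truth$planted_contrast == "1+"]
  expect_true(all(res$passed_sig[match(planted, res$gene)]))

  # an infinite threshold flags nothing and runs no tests
  res_inf <- select_contrast_degs(d, ctr, fc_threshold = Inf)
  expect_equal(sum(res_inf$passed_fc), 0)
  expect_true(all(is.na(res_inf$p_raw)))

  # permutation of sample order leaves the screen unchanged
  perm <- sample(ncol(d$matrix))
  d_perm <- expression_dataset(d$matrix[, perm], d$samples[perm, ])
  res_perm <- select_contrast_degs(d_perm, her2_contrast(d_perm, "1+"))
  expect_equal(res_perm$log2fc, res$log2fc)
  expect_equal(res_perm$p_raw, res$p_raw)

  # empty-category contrast is skipped with a warning, result empty
  expect_warning(ctr0 <- her2_contrast(
    make_ds(matrix(1:4, 1, dimnames = list("g", paste0("s", 1:4))),
            c("0", "0", "1+", "1+")), "2+"), "skipped")
  expect_null(ctr0)
  expect_equal(nrow(select_contrast_degs(d, NULL)), 0)
})

test_that("venn_specific_genes reproduces the worked example in both modes", {
  sets <- list("1+" = c("a", "b", "c"), "2+" = c("b", "d"), "low" = "e")
  for (mode in c("hierarchical", "exclusive")) {
    vp <- venn_specific_genes(sets, mode = mode)
    expect_setequal(vp$specific[["1+"]], c("a", "c"))
    expect_setequal(vp$specific[["2+"]], "d")
    expect_setequal(vp$specific[["low"]], "e")
    expect_equal(vp$overlap$gene, "b")
    # specific cells are pairwise disjoint and covered by the union of sigs
    all_spec <- unlist(vp$specific)
    expect_equal(anyDuplicated(all_spec), 0)
    expect_true(all(all_spec %in% unlist(sets)))
  }
  # degenerate inputs
  vp0 <- venn_specific_genes(list("1+" = character(), "low" = character()))
  expect_true(all(lengths(vp0$specific) == 0))
  vp1 <- venn_specific_genes(list("2+" = c("x", "y")))
  expect_setequal(vp1$specific[["2+"]], c("x", "y"))
})

test_that("sign-aware attribution resolves rest-dilution patterns", {
  syn <- small_synthetic(seed = 13, n_per_cat = 30)
  screens <- suppressMessages(screen_dataset(syn$datasets[[1]]))
  vp <- venn_specific_genes(screens, mode = "hierarchical")
  gt <- syn$ground_truth[syn$ground_truth$planted_contrast != "ordinal", ]
  hit <- mapply(function(g, k) g %in% vp$specific[[k]], gt$gene,
                gt$planted_contrast)
  expect_true(mean(hit) >= 8 / 9)
  # a low-planted gene is significantly DOWN in 0-vs-others by dilution,
  # yet must not be disqualified from the low cell
  lowg <- gt$gene[gt$planted_contrast == "low"][1]
  expect_true(screens[["0"]]$passed_sig[screens[["0"]]$gene == lowg])
  expect_lt(screens[["0"]]$log2fc[screens[["0"]]$gene == lowg], 0)
  expect_true(lowg %in% vp$specific[["low"]])
  # plain exclusivity cannot place it anywhere
  vpx <- venn_specific_genes(screens, mode = "exclusive")
  expect_false(lowg %in% unlist(vpx$specific))
})

test_that("merge_discovery unions, deduplicates and detects conflicts", {
  mk <- function(sets) structure(list(specific = sets,
                                      overlap = data.frame(gene = character(),
                                                           pattern = character()),
                                      sig_sets = sets, mode = "hierarchical"),
                                 class = "VennPartition")
  p1 <- mk(list("1+" = c("a1", "a2", "a3"),
                "2+" = paste0("b", 1:8), "low" = "CPLX1"))
  p2 <- mk(list("1+" = paste0("c", 1:8), "2+" = character(),
                "low" = character()))
  merged <- merge_discovery(list(INT1 = p1, INT2 = p2))
  expect_equal(nrow(merged), 20)
  expect_equal(as.vector(table(merged$category)[c("1+", "2+", "low")]),
               c(11, 8, 1))
  expect_equal(anyDuplicated(merged$gene), 0)
  # same gene, same category, two datasets: kept once with joint source
  dup <- merge_discovery(list(A = mk(list("1+" = "g")),
                              B = mk(list("1+" = "g"))))
  expect_equal(nrow(dup), 1)
  expect_equal(dup$source, "A+B")
  # category conflict across datasets
  expect_error(merge_discovery(list(A = mk(list("1+" = "g")),
                                    B = mk(list("2+" = "g")))),
               "different categories.*g")
  expect_warning(ok <- merge_discovery(list(A = mk(list("1+" = "g")),
                                            B = mk(list("2+" = "g"))),
                                       on_conflict = "drop"), "dropped")
  expect_equal(nrow(ok), 0)
})
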