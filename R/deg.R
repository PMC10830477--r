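# One-vs-rest differential-expression screening and Venn selection.
#
# Screening is the two-stage filter used to nominate category-specific
# genes: (1) flag genes with |log2 fold change| above a threshold for a
# one-vs-rest contrast of the HER2 IHC categories, (2) test only the flagged
# genes with the two-sided Wilcoxon rank-sum test and Bonferroni-adjust
# within the contrast's flagged family. The Venn step assigns significant
# genes to exactly-one-contrast "specific" cells.

CONTRAST_NAMES <- c("0", "1+", "2+", "3+", "low")

#' Build a one-vs-rest contrast over HER2 IHC categories
#'
#' @param dataset An [expression_dataset()].
#' @param name Focal category: `"0"`, `"1+"`, `"2+"`, `"3+"`, or `"low"`
#'   (focal = 1+ and 2+ samples jointly).
#' @return A list with `name`, `focal` and `rest` sample-id vectors
#'   (disjoint, jointly covering the dataset), or `NULL` with a warning when
#'   the focal or rest side is empty (e.g. a 2+ contrast in a cohort without
#'   2+ tumors).
#' @export
her2_contrast <- function(dataset, name) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  name <- match.arg(name, CONTRAST_NAMES)
  cat <- dataset$samples$ihc_score
  focal_mask <- if (name == "low") cat %in% c("1+", "2+") else cat == name
  focal <- dataset$samples$sample_id[focal_mask]
  rest <- dataset$samples$sample_id[!focal_mask]
  if (!length(focal) || !length(rest)) {
    warning(sprintf("contrast '%s-vs-others' skipped: empty %s group", name,
                    if (length(focal)) "rest" else "focal"))
    return(NULL)
  }
  list(name = name, focal = focal, rest = rest)
}

#' Log2 fold change of a one-vs-rest contrast
#'
#' Difference of group means on the log2 scale, `mean(focal) - mean(rest)`
#' (the standard microarray convention; exact for additive planted effects).
#'
#' @param dataset An [expression_dataset()] (values already log2).
#' @param contrast A contrast from [her2_contrast()].
#' @param genes Genes to compute; default all.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(dataset, contrast, genes = dataset$genes) {
  if (is.null(contrast) || !length(contrast$focal) || !length(contrast$rest))
    stop("empty group in contrast '", contrast$name %||% "?", "'")
  m <- dataset$matrix[genes, , drop = FALSE]
  rowMeans(m[, contrast$focal, drop = FALSE]) -
    rowMeans(m[, contrast$rest, drop = FALSE])
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the smaller group has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. When every value in both groups is identical the
#' test is degenerate and returns p = 1 with a warning.
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @return Two-sided p-value in \[0, 1\].
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L) {
    warning("rank_sum_test: all values identical in both groups; p = 1")
    return(1)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8L
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  min(p, 1)
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p_values)`.
#' @return `pmin(1, p_values * m)`.
#' @export
bonferroni_adjust <- function(p_values, m) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  if (m < length(p_values))
    stop("Bonferroni family size m (", m, ") smaller than number of tests (",
         length(p_values), ")")
  pmin(1, p_values * m)
}

#' Two-stage screen of one contrast
#'
#' Stage 1 flags genes with `|log2fc| > fc_threshold`; stage 2 applies
#' [rank_sum_test()] to the flagged genes only and Bonferroni-adjusts over
#' the flagged family of this contrast (set `family = "all"` to adjust over
#' all genes instead). A gene passes (`passed_sig`) when its adjusted p-value
#' is below `alpha`.
#'
#' @param dataset An [expression_dataset()].
#' @param contrast From [her2_contrast()]; `NULL` yields an empty result.
#' @param fc_threshold Absolute log2 fold-change filter (default 1).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param family `"flagged"` (default) or `"all"`: Bonferroni family size.
#' @return `data.frame` of class `ContrastResult` with columns `gene`,
#'   `log2fc`, `p_raw`, `p_adj`, `passed_fc`, `passed_sig` (p columns `NA`
#'   for unflagged genes) and attributes `contrast`, `alpha`, `fc_threshold`.
#' @export
select_contrast_degs <- function(dataset, contrast, fc_threshold = 1,
                                 alpha = 0.05,
                                 family = c("flagged", "all")) {
  family <- match.arg(family)
  stopifnot(inherits(dataset, "ExpressionDataset"),
            is_scalar_number(alpha), alpha > 0, alpha < 1)
  empty <- function(name) {
    res <- data.frame(gene = character(), log2fc = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      passed_fc = logical(), passed_sig = logical(),
                      stringsAsFactors = FALSE)
    structure(res, class = c("ContrastResult", "data.frame"),
              contrast = name, alpha = alpha, fc_threshold = fc_threshold)
  }
  if (is.null(contrast)) return(empty(NA_character_))
  if (length(contrast$focal) < 2 || length(contrast$rest) < 2)
    stop("contrast '", contrast$name, "' needs >= 2 samples per group")
  fc <- log2_fold_change(dataset, contrast)
  passed_fc <- is.finite(fc) & abs(fc) > fc_threshold
  p_raw <- rep(NA_real_, length(fc))
  if (any(passed_fc)) {
    xmat <- dataset$matrix[, contrast$focal, drop = FALSE]
    ymat <- dataset$matrix[, contrast$rest, drop = FALSE]
    for (i in which(passed_fc))
      p_raw[i] <- rank_sum_test(xmat[i, ], ymat[i, ])
  }
  m <- if (family == "flagged") sum(passed_fc) else length(fc)
  p_adj <- rep(NA_real_, length(fc))
  if (any(passed_fc))
    p_adj[passed_fc] <- bonferroni_adjust(p_raw[passed_fc], m)
  res <- data.frame(gene = dataset$genes, log2fc = unname(fc),
                    p_raw = p_raw, p_adj = p_adj, passed_fc = passed_fc,
                    passed_sig = !is.na(p_adj) & p_adj < alpha,
                    stringsAsFactors = FALSE)
  structure(res, class = c("ContrastResult", "data.frame"),
            contrast = contrast$name, alpha = alpha,
            fc_threshold = fc_threshold)
}

#' Screen all feasible one-vs-rest contrasts of a dataset
#'
#' Runs [select_contrast_degs()] for each requested contrast; contrasts with
#' an empty focal category (e.g. 2+ in a cohort lacking 2+ tumors) are
#' skipped with a warning and yield an empty result.
#'
#' @inheritParams select_contrast_degs
#' @param contrasts Contrast names, default all five.
#' @return Named list of `ContrastResult`s.
#' @export
screen_dataset <- function(dataset, contrasts = CONTRAST_NAMES,
                           fc_threshold = 1, alpha = 0.05,
                           family = c("flagged", "all")) {
  family <- match.arg(family)
  res <- lapply(contrasts, function(nm) {
    ctr <- withCallingHandlers(
      her2_contrast(dataset, nm),
      warning = function(w) {
        message(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    select_contrast_degs(dataset, ctr, fc_threshold = fc_threshold,
                         alpha = alpha, family = family)
  })
  names(res) <- contrasts
  res
}

#' Venn assignment of significant genes to category-specific cells
#'
#' Given per-contrast screening results, assigns each significant gene to a
#' "specific" cell or to the overlap. Two attribution modes:
#'
#' * `"hierarchical"` (default): sign-aware attribution that accounts for
#'   rest-dilution. In a one-vs-rest scheme a gene truly up in category K is
#'   mechanically down in every complementary contrast (the rest of K'
#'   contains the K samples), and a gene up in the low union (1+/2+) is up
#'   in the 1+ and 2+ contrasts individually and down in 0 and 3+. Such
#'   dilution-consistent significance elsewhere is corroborating, not
#'   disqualifying. Concretely, a gene is a candidate for single category K
#'   when it is significant in K and every other significant single-category
#'   contrast has the opposite fold-change sign; a unique candidacy wins,
#'   and multiple candidacies are broken toward the largest absolute fold
#'   change. The low cell collects genes significant in the low contrast
#'   with no single-category candidacy whose single-category fold-change
#'   signs all match the low sign for 1+/2+ and oppose it for 0/3+ (the
#'   bell-shape pattern). Everything else significant lands in `overlap`.
#'   Requires `ContrastResult` inputs (fold changes); plain gene sets fall
#'   back to a sign-blind variant in which the low contrast simply does not
#'   compete with the single categories.
#' * `"exclusive"`: plain set arithmetic — a gene is specific to contrast K
#'   iff significant in K and in no other contrast of interest.
#'
#' Genes significant somewhere but in no specific cell are reported in
#' `overlap` with their significance pattern.
#'
#' @param results Named list of `ContrastResult`s (names are contrast
#'   labels), or a named list of character vectors of significant genes.
#' @param contrasts_of_interest Which contrasts compete; default all present.
#' @param mode Attribution rule, see above.
#' @return An object of class `VennPartition`: list with `specific` (named
#'   list of gene vectors, pairwise disjoint), `overlap` (`data.frame` gene /
#'   pattern), `sig_sets` and `mode`.
#' @export
venn_specific_genes <- function(results,
                                contrasts_of_interest = names(results),
                                mode = c("hierarchical", "exclusive")) {
  mode <- match.arg(mode)
  stopifnot(length(contrasts_of_interest) >= 1,
            all(contrasts_of_interest %in% names(results)))
  sig_sets <- lapply(results[contrasts_of_interest], function(r) {
    if (is.character(r)) unique(r)
    else r$gene[r$passed_sig]
  })
  cats <- intersect(c("0", "1+", "2+", "3+"), names(sig_sets))
  has_low <- "low" %in% names(sig_sets)
  has_fc <- all(vapply(results[contrasts_of_interest],
                       function(r) !is.character(r), TRUE))
  specific <- stats::setNames(vector("list", length(sig_sets)),
                              names(sig_sets))
  for (k in names(specific)) specific[[k]] <- character()
  if (mode == "exclusive") {
    for (k in names(sig_sets)) {
      others <- unlist(sig_sets[setdiff(names(sig_sets), k)], use.names = FALSE)
      specific[[k]] <- setdiff(sig_sets[[k]], others)
    }
  } else if (!has_fc || !has_low) {
    # sign-blind fallback: low does not compete with the single categories
    for (k in cats) {
      others <- unlist(sig_sets[setdiff(cats, k)], use.names = FALSE)
      specific[[k]] <- setdiff(sig_sets[[k]], others)
    }
    if (has_low)
      specific[["low"]] <- setdiff(sig_sets[["low"]],
                                   unlist(sig_sets[cats], use.names = FALSE))
  } else {
    fc <- lapply(results[contrasts_of_interest], function(r)
      stats::setNames(r$log2fc, r$gene))
    all_sig <- unique(unlist(sig_sets, use.names = FALSE))
    for (g in all_sig) {
      in_set <- vapply(sig_sets, function(s) g %in% s, TRUE)
      sig_cats <- cats[in_set[cats]]
      sgn <- vapply(contrasts_of_interest, function(k)
        sign(fc[[k]][g] %||% NA_real_), 0)
      # single-category candidacies: every other significant single
      # category must carry the opposite (dilution-consistent) sign
      cand <- sig_cats[vapply(sig_cats, function(k)
        all(sgn[setdiff(sig_cats, k)] == -sgn[k]), TRUE)]
      if (length(cand) > 1)  # tie-break: strongest effect wins
        cand <- cand[which.max(vapply(cand, function(k) abs(fc[[k]][g]), 0))]
      if (length(cand) == 1) {
        specific[[cand]] <- c(specific[[cand]], g)
      } else if (in_set[["low"]] && length(sig_cats) == 0) {
        specific[["low"]] <- c(specific[["low"]], g)
      } else if (in_set[["low"]]) {
        bell <- all(sgn[intersect(sig_cats, c("1+", "2+"))] == sgn[["low"]]) &&
          all(sgn[intersect(sig_cats, c("0", "3+"))] == -sgn[["low"]])
        if (bell) specific[["low"]] <- c(specific[["low"]], g)
      }
    }
  }
  all_sig <- unique(unlist(sig_sets, use.names = FALSE))
  in_specific <- unique(unlist(specific, use.names = FALSE))
  leftover <- setdiff(all_sig, in_specific)
  pattern <- vapply(leftover, function(g)
    paste(names(sig_sets)[vapply(sig_sets, function(s) g %in% s, TRUE)],
          collapse = "&"), "")
  structure(list(
    specific = specific,
    overlap = data.frame(gene = leftover, pattern = unname(pattern),
                         stringsAsFactors = FALSE),
    sig_sets = sig_sets, mode = mode), class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition (", x$mode, " attribution)\n", sep = "")
  for (k in names(x$specific))
    cat(sprintf("  %-4s specific: %d gene(s)\n", k, length(x$specific[[k]])))
  cat(sprintf("  overlap: %d gene(s)\n", nrow(x$overlap)))
  invisible(x)
}

#' Merge category-specific genes across discovery datasets
#'
#' Union of the requested specific cells over several datasets' Venn
#' partitions, each gene tagged with its category and source dataset(s). A
#' gene specific to the same category in two datasets is kept once; a gene
#' assigned to different categories in different datasets is a conflict.
#'
#' @param partitions Named list of `VennPartition`s (names = dataset labels).
#' @param categories Specific cells to merge; default `"1+"`, `"2+"`,
#'   `"low"` (the cells the signature draws from; 0- and 3+-specific cells
#'   are diagnostic only).
#' @param on_conflict `"error"` (default) or `"drop"` (warn and drop the
#'   conflicted gene).
#' @return `data.frame` of class `DiscoverySelection` with columns `gene`,
#'   `category`, `source`; genes unique.
#' @export
merge_discovery <- function(partitions, categories = c("1+", "2+", "low"),
                            on_conflict = c("error", "drop")) {
  on_conflict <- match.arg(on_conflict)
  stopifnot(length(partitions) >= 1)
  if (is.null(names(partitions)) || any(names(partitions) == ""))
    names(partitions) <- paste0("dataset", seq_along(partitions))
  rows <- do.call(rbind, lapply(names(partitions), function(lab) {
    part <- partitions[[lab]]
    stopifnot(inherits(part, "VennPartition"))
    do.call(rbind, lapply(intersect(categories, names(part$specific)),
                          function(k) {
      genes <- part$specific[[k]]
      if (!length(genes)) return(NULL)
      data.frame(gene = genes, category = k, source = lab,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows))
    rows <- data.frame(gene = character(), category = character(),
                       source = character(), stringsAsFactors = FALSE)
  if (nrow(rows)) {
    cat_by_gene <- tapply(rows$category, rows$gene,
                          function(v) length(unique(v)))
    conflicted <- names(cat_by_gene)[cat_by_gene > 1]
    if (length(conflicted)) {
      msg <- paste0("gene(s) assigned to different categories in different datasets: ",
                    paste(conflicted, collapse = ", "))
      if (on_conflict == "error") stop(msg)
      warning(msg, "; dropped")
      rows <- rows[!rows$gene %in% conflicted, , drop = FALSE]
    }
  }
  if (nrow(rows)) {
    agg <- stats::aggregate(source ~ gene + category, data = rows,
                            FUN = function(s) paste(sort(unique(s)),
                                                    collapse = "+"))
    agg <- agg[order(match(agg$category, CONTRAST_NAMES), agg$gene), ]
    rows <- agg[, c("gene", "category", "source")]
    rownames(rows) <- NULL
  }
  structure(rows, class = c("DiscoverySelection", "data.frame"))
}

#' Export contrast results or a Venn partition as TSV
#'
#' @param x A `ContrastResult`, list of them, or `VennPartition`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(x, path) {
  if (inherits(x, "VennPartition")) {
    rows <- do.call(rbind, lapply(names(x$specific), function(k)
      if (length(x$specific[[k]]))
        data.frame(gene = x$specific[[k]], cell = k,
                   stringsAsFactors = FALSE)))
    if (nrow(x$overlap))
      rows <- rbind(rows, data.frame(gene = x$overlap$gene,
                                     cell = paste0("overlap:", x$overlap$pattern)))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (inherits(x, "ContrastResult")) x <- list(x)
    rows <- do.call(rbind, lapply(x, function(r)
      cbind(contrast = attr(r, "contrast"), as.data.frame(r))))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
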