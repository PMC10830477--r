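# PC1-weighted signature construction and scoring.
#
# The signature is the first principal component of the category-specific
# genes' correlation matrix on the fitting cohort: per-sample score =
# orientation * sum_g w_g * z_g, with z the standardized log2 expression and
# w the unit-norm leading eigenvector. The orientation sign is fixed so that
# HER2-low samples score above HER2-zero samples on the fitting cohort.

#' Standardize the expression of selected genes
#'
#' Per-gene z-transform `(x - mean) / sd`. In `fit` mode the mean and sd are
#' estimated from `dataset` itself and returned; in `apply` mode the supplied
#' `params` are used (the train-parameter transfer rule).
#'
#' @param dataset An [expression_dataset()].
#' @param genes Genes to standardize; all must be present unless
#'   `missing_genes = "drop"`, which drops absentees with a warning.
#' @param mode `"fit"` or `"apply"`.
#' @param params For `apply` mode: list with numeric named vectors `mean`
#'   and `sd` (as returned by fit mode).
#' @param missing_genes `"error"` (default) or `"drop"`.
#' @return List with `z` (genes x samples standardized matrix) and `params`.
#' @export
standardize_genes <- function(dataset, genes, mode = c("fit", "apply"),
                              params = NULL,
                              missing_genes = c("error", "drop")) {
  mode <- match.arg(mode)
  missing_genes <- match.arg(missing_genes)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  absent <- setdiff(genes, dataset$genes)
  if (length(absent)) {
    if (missing_genes == "error")
      stop("gene(s) absent from dataset: ", paste(absent, collapse = ", "))
    warning("dropping ", length(absent), " absent gene(s): ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  if (!length(genes)) stop("no genes left to standardize")
  m <- dataset$matrix[genes, , drop = FALSE]
  if (mode == "fit") {
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
  } else {
    if (is.null(params$mean) || is.null(params$sd))
      stop("apply mode requires params$mean and params$sd")
    if (!all(genes %in% names(params$mean)))
      stop("params lack standardization values for: ",
           paste(setdiff(genes, names(params$mean)), collapse = ", "))
    mu <- params$mean[genes]
    sd <- params$sd[genes]
  }
  zero_sd <- names(which(sd <= 0 | !is.finite(sd)))
  if (length(zero_sd))
    stop("zero or undefined standard deviation for gene(s): ",
         paste(zero_sd, collapse = ", "))
  z <- (m - mu) / sd
  list(z = z, params = list(mean = stats::setNames(as.numeric(mu), genes),
                            sd = stats::setNames(as.numeric(sd), genes)))
}

#' Fit the PC1 signature model
#'
#' Computes the Pearson correlation matrix of the signature genes on the
#' fitting dataset, eigendecomposes it and takes the leading eigenvector
#' (unit norm) as the gene weights. The fraction of variance explained is
#' `lambda_1 / sum(lambda)`. The eigenvector's sign is intrinsically
#' arbitrary; it is fixed so that the mean score of HER2-low samples exceeds
#' the mean score of HER2-zero samples in the fitting dataset (the
#' orientation under which "high score" means "HER2-low-like").
#'
#' @param dataset Fitting [expression_dataset()]; should have both HER2-low
#'   and HER2-zero samples to orient the score.
#' @param genes Signature genes (>= 2), all present in `dataset`.
#' @param eigen_gap_tol Relative tolerance below which a tie between the two
#'   leading eigenvalues is treated as an error (ill-defined PC1).
#' @return An object of class `SignatureModel`: `genes`, `train_mean`,
#'   `train_sd`, `weights` (unit norm), `orientation` (+1/-1),
#'   `explained_share`, `fit_cohort`.
#' @export
fit_signature <- function(dataset, genes, eigen_gap_tol = 1e-8) {
  stopifnot(inherits(dataset, "ExpressionDataset"), length(genes) >= 2)
  n <- nrow(dataset$samples)
  if (n < length(genes) + 2)
    warning(sprintf("fitting %d-gene PCA on only %d samples; weights will be unstable",
                    length(genes), n))
  std <- standardize_genes(dataset, genes, mode = "fit")
  cmat <- stats::cor(t(dataset$matrix[genes, , drop = FALSE]))
  if (any(!is.finite(cmat)))
    stop("correlation matrix not computable (constant gene?)")
  eg <- eigen(cmat, symmetric = TRUE)
  gap <- (eg$values[1] - eg$values[2]) / max(eg$values[1], .Machine$double.eps)
  if (gap < eigen_gap_tol)
    stop("leading eigenvalues tied (relative gap ", format(gap),
         "); PC1 is not identifiable - review the gene set")
  w <- eg$vectors[, 1]
  w <- w / sqrt(sum(w^2))
  names(w) <- genes
  model <- structure(list(
    genes = genes,
    train_mean = std$params$mean, train_sd = std$params$sd,
    weights = w, orientation = 1,
    explained_share = eg$values[1] / sum(eg$values),
    fit_cohort = paste(unique(dataset$samples$cohort), collapse = "+")),
    class = "SignatureModel")
  grp <- classify_her2_group(dataset$samples$ihc_score,
                             dataset$samples$ish_amplified)
  raw <- drop(crossprod(std$z, w))
  m_low <- mean(raw[grp == "low"])
  m_zero <- mean(raw[grp == "zero"])
  if (!is.finite(m_low) || !is.finite(m_zero)) {
    warning("cannot orient signature (missing HER2-low or HER2-zero samples); keeping +1")
  } else if (m_low < m_zero) {
    model$orientation <- -1
  }
  model
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %d genes, PC1 explains %.1f%% (fit on %s)\n",
              length(x$genes), 100 * x$explained_share, x$fit_cohort))
  top <- utils::head(order(abs(x$weights), decreasing = TRUE), 5)
  cat("top |weights|: ",
      paste(sprintf("%s=%.3f", x$genes[top],
                    x$orientation * x$weights[top]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Score samples with a fitted signature model
#'
#' `score_i = orientation * sum_g weights_g * z_{g,i}`. With
#' `standardization_mode = "per-dataset"` (default) genes are re-standardized
#' within the scored dataset — the cross-platform transfer rule, invariant to
#' per-gene affine platform effects. `"train-params"` reuses the fitting
#' cohort's means and standard deviations.
#'
#' @param model A [fit_signature()] model.
#' @param dataset Dataset to score.
#' @param standardization_mode `"per-dataset"` or `"train-params"`.
#' @param missing_genes Passed to [standardize_genes()]; with `"drop"`,
#'   weights of the remaining genes are rescaled to unit norm (prominent
#'   warning).
#' @return `data.frame` of class `SignatureScores` with `sample_id`,
#'   `cohort`, `score`, and attribute `standardization_mode`.
#' @export
score_samples <- function(model, dataset,
                          standardization_mode = c("per-dataset", "train-params"),
                          missing_genes = c("error", "drop")) {
  standardization_mode <- match.arg(standardization_mode)
  missing_genes <- match.arg(missing_genes)
  stopifnot(inherits(model, "SignatureModel"),
            inherits(dataset, "ExpressionDataset"))
  std <- if (standardization_mode == "per-dataset")
    standardize_genes(dataset, model$genes, mode = "fit",
                      missing_genes = missing_genes)
  else
    standardize_genes(dataset, model$genes, mode = "apply",
                      params = list(mean = model$train_mean, sd = model$train_sd),
                      missing_genes = missing_genes)
  genes_used <- rownames(std$z)
  w <- model$weights[genes_used]
  if (length(genes_used) < length(model$genes)) {
    warning(sprintf("scoring with %d of %d signature genes; weights renormalized to unit norm",
                    length(genes_used), length(model$genes)))
    w <- w / sqrt(sum(w^2))
  }
  score <- model$orientation * drop(crossprod(std$z, w))
  res <- data.frame(sample_id = dataset$samples$sample_id,
                    cohort = dataset$samples$cohort,
                    score = unname(score), stringsAsFactors = FALSE)
  structure(res, class = c("SignatureScores", "data.frame"),
            standardization_mode = standardization_mode)
}

#' Serialize / restore a signature model as JSON
#'
#' Numbers are written with 17 significant digits, so a write/read round
#' trip reproduces weights and standardization parameters bit-exactly.
#'
#' @param model A `SignatureModel`.
#' @param path JSON path.
#' @return `write_signature_model`: invisibly, `path`;
#'   `read_signature_model`: the restored `SignatureModel`.
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "SignatureModel"))
  payload <- list(
    genes = model$genes,
    train_mean = as.list(model$train_mean),
    train_sd = as.list(model$train_sd),
    weights = as.list(model$weights),
    orientation = model$orientation,
    explained_share = model$explained_share,
    fit_cohort = model$fit_cohort,
    format = "her2lowsig/SignatureModel/v1")
  write_json_exact(payload, path)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  stopifnot(identical(p$format, "her2lowsig/SignatureModel/v1"))
  structure(list(
    genes = as.character(p$genes),
    train_mean = unlist(p$train_mean), train_sd = unlist(p$train_sd),
    weights = unlist(p$weights), orientation = as.numeric(p$orientation),
    explained_share = as.numeric(p$explained_share),
    fit_cohort = p$fit_cohort),
    class = "SignatureModel")
}
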