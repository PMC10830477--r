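# Multi-cohort synthetic expression generator.
#
# Emulates the structure of the development data: several cohorts with fixed
# HER2 IHC category counts, Gaussian log2 expression with per-cohort platform
# offsets, planted category-specific genes (additive log2 shifts in the
# focal category of a one-vs-rest contrast), an ERBB2-like gene whose mean
# tracks the IHC category ordinally, and a latent per-sample factor loading
# on the HER2-low planted genes. Ground truth (which genes were planted, for
# which contrast, with what effect) is carried as a sidecar table so that
# recovery metrics are computable.

#' Configuration for the synthetic cohort generator
#'
#' @param n_per_category_per_cohort Integer matrix of sample counts, cohorts
#'   in rows, HER2 IHC categories `0,1+,2+,3+` in columns. Row names label
#'   the cohorts.
#' @param n_background_genes Number of null background genes (no planted
#'   effect).
#' @param planted_sets Named list over target contrasts (any of `"1+"`,
#'   `"2+"`, `"low"`), each a `list(n = count, delta = log2 effect)`. The
#'   effect is added to the gene's expression in every sample of the focal
#'   category (`"low"` means categories 1+ and 2+).
#' @param erbb2_category_means Four numbers, the mean log2 expression of the
#'   ERBB2-like benchmark gene in categories 0, 1+, 2+, 3+; must be
#'   nondecreasing (ordinal tracking).
#' @param bellshape_loading Nonnegative loading linking every planted
#'   signature gene to a latent per-sample "HER2-low factor"
#'   `h ~ N(m, 1)` with mean `m = 1` in categories 1+ and 2+ and `m = 0` in
#'   0 and 3+. The shared factor (i) correlates the 1+, 2+ and low gene
#'   blocks so the fitted first principal component captures one coherent
#'   axis rather than splitting into orthogonal per-category axes, and
#'   (ii) gives that axis the bell shape across IHC categories (high score
#'   in 1+/2+, low in 0/3+).
#' @param noise_sd Residual standard deviation of log2 expression (> 0).
#' @param cohort_offset_sd Standard deviation of per-gene, per-cohort
#'   platform offsets (0 disables them).
#' @param hr_positive_prob_per_category Four probabilities of HR-positive
#'   status, one per IHC category (confounding knob).
#' @param seed Integer seed; generation is reproducible given the seed.
#'
#' @return An object of class `SyntheticConfig`.
#' @seealso [default_synthetic_config()], [generate_cohorts()]
#' @export
synthetic_config <- function(n_per_category_per_cohort,
                             n_background_genes = 1000,
                             planted_sets = list(
                               "1+"  = list(n = 11, delta = 1.5),
                               "2+"  = list(n = 8,  delta = 1.5),
                               "low" = list(n = 1,  delta = 1.5)),
                             erbb2_category_means = c(8, 8.5, 9, 11.5),
                             bellshape_loading = 0.8,
                             noise_sd = 0.5,
                             cohort_offset_sd = 0.25,
                             hr_positive_prob_per_category = c(0.28, 0.74, 0.74, 0.63),
                             seed = 1L) {
  counts <- as.matrix(n_per_category_per_cohort)
  if (ncol(counts) != 4L)
    stop("n_per_category_per_cohort needs 4 columns (categories 0, 1+, 2+, 3+)")
  colnames(counts) <- IHC_LEVELS
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("COHORT", seq_len(nrow(counts)))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("sample counts must be nonnegative integers")
  if (sum(counts) == 0) stop("total sample count is zero")
  stopifnot(is_scalar_number(noise_sd), noise_sd > 0,
            is_scalar_number(cohort_offset_sd), cohort_offset_sd >= 0,
            is_scalar_number(bellshape_loading), bellshape_loading >= 0,
            length(erbb2_category_means) == 4L,
            length(hr_positive_prob_per_category) == 4L,
            all(hr_positive_prob_per_category >= 0),
            all(hr_positive_prob_per_category <= 1))
  if (is.unsorted(erbb2_category_means))
    stop("erbb2_category_means must be nondecreasing across IHC categories")
  bad <- setdiff(names(planted_sets), c("1+", "2+", "low"))
  if (length(bad))
    stop("planted_sets keys must be among '1+', '2+', 'low'; got: ",
         paste(bad, collapse = ", "))
  for (ps in planted_sets)
    stopifnot(is_scalar_number(ps$n), ps$n >= 0, is_scalar_number(ps$delta))
  n_planted <- sum(vapply(planted_sets, function(p) p$n, 0))
  if (n_planted > n_background_genes)
    stop("more planted genes than background genes requested")
  structure(list(
    n_per_category_per_cohort = counts,
    n_background_genes = as.integer(n_background_genes),
    planted_sets = planted_sets,
    erbb2_category_means = as.numeric(erbb2_category_means),
    bellshape_loading = bellshape_loading,
    noise_sd = noise_sd, cohort_offset_sd = cohort_offset_sd,
    hr_positive_prob_per_category = as.numeric(hr_positive_prob_per_category),
    seed = as.integer(seed)), class = "SyntheticConfig")
}

#' Default synthetic configuration mirroring the development population
#'
#' Per-cohort HER2 IHC category counts equal to the development population's
#' (INT1 = 33/62/12/18, INT2 = 52/32/0/0, INT3 = 25/26/30/14; 304 samples in
#' total), with the documented default effect sizes: planted log2 shifts of
#' 1.5 for 11 genes in 1+, 8 genes in 2+ and 1 gene in HER2-low, residual SD
#' 0.5, and an ordinal ERBB2-like gene. See the methods vignette for the
#' rationale behind each default.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A `SyntheticConfig`.
#' @export
default_synthetic_config <- function(seed = 1L, ...) {
  counts <- rbind(INT1 = c(33, 62, 12, 18),
                  INT2 = c(52, 32, 0, 0),
                  INT3 = c(25, 26, 30, 14))
  synthetic_config(n_per_category_per_cohort = counts, seed = seed, ...)
}

#' Generate synthetic expression cohorts
#'
#' Expression of background gene g in sample i of cohort c is
#' `mu_g + o_gc + eps`, with `mu_g ~ N(7, 1)` a gene baseline shared across
#' cohorts, `o_gc ~ N(0, cohort_offset_sd^2)` a per-gene platform offset and
#' `eps ~ N(0, noise_sd^2)`. A gene planted for contrast K additionally gains
#' `delta` in every sample whose category lies in K (K = low means 1+ and
#' 2+); every planted gene additionally gains `bellshape_loading * h_i`,
#' where `h_i` is the latent HER2-low factor (unit mean in 1+/2+, zero mean
#' in 0/3+, unit variance). The ERBB2-like benchmark gene
#' (`ERBB2`) has category-specific means instead of a baseline. HR status is
#' drawn per category from the configured probabilities.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `SyntheticCohorts`: list with `datasets` (one
#'   [expression_dataset()] per cohort), `ground_truth` (`data.frame` of
#'   gene, planted_contrast, delta for the planted and ERBB2-like genes) and
#'   `config`.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  counts <- config$n_per_category_per_cohort
  planted <- config$planted_sets
  gene_names <- c(
    unlist(lapply(names(planted), function(k) {
      n <- planted[[k]]$n
      if (n == 0) return(character())
      sprintf("PL%s_%03d", toupper(sub("\\+", "P", k)), seq_len(n))
    }), use.names = FALSE),
    "ERBB2",
    sprintf("BG%04d", seq_len(config$n_background_genes)))
  planted_of <- rep(NA_character_, length(gene_names))
  idx <- 1L
  for (k in names(planted)) {
    n <- planted[[k]]$n
    if (n > 0) planted_of[idx:(idx + n - 1L)] <- k
    idx <- idx + n
  }
  n_genes <- length(gene_names)
  erbb2_row <- match("ERBB2", gene_names)

  datasets <- with_seed(config$seed, {
    mu <- stats::rnorm(n_genes, mean = 7, sd = 1)
    mu[erbb2_row] <- 0  # replaced by category means below
    lapply(rownames(counts), function(co) {
      n_cat <- counts[co, ]
      n <- sum(n_cat)
      if (n == 0) return(NULL)
      category <- rep(IHC_LEVELS, times = n_cat)
      offset <- if (config$cohort_offset_sd > 0)
        stats::rnorm(n_genes, sd = config$cohort_offset_sd) else numeric(n_genes)
      hr_prob <- config$hr_positive_prob_per_category[match(category, IHC_LEVELS)]
      hr <- ifelse(stats::runif(n) < hr_prob, "positive", "negative")
      # latent HER2-low factor: unit mean in the 1+/2+ categories, zero in
      # 0/3+, unit-variance noise; amplitude set by bellshape_loading
      h <- as.numeric(category %in% c("1+", "2+")) + stats::rnorm(n)
      mat <- mu + offset +
        matrix(stats::rnorm(n_genes * n, sd = config$noise_sd), n_genes, n)
      for (k in names(planted)) {
        rows <- which(planted_of == k)
        if (!length(rows)) next
        focal <- if (k == "low") category %in% c("1+", "2+")
                 else category == k
        mat[rows, focal] <- mat[rows, focal] + planted[[k]]$delta
      }
      # latent per-sample factor shared by all planted signature genes:
      # couples the category blocks so that a single PC1 axis exists
      sig_rows <- which(!is.na(planted_of))
      if (length(sig_rows) && config$bellshape_loading > 0)
        mat[sig_rows, ] <- mat[sig_rows, ] +
          config$bellshape_loading * matrix(h, length(sig_rows), n,
                                            byrow = TRUE)
      mat[erbb2_row, ] <- mat[erbb2_row, ] +
        config$erbb2_category_means[match(category, IHC_LEVELS)]
      dimnames(mat) <- list(gene_names,
                            sprintf("%s_S%04d", co, seq_len(n)))
      ann <- data.frame(
        sample_id = colnames(mat), cohort = co, ihc_score = category,
        ish_amplified = "unknown", hr_status = hr, pam50 = "unknown",
        grade = NA_character_, size_class = NA_character_,
        age_years = NA_real_, stringsAsFactors = FALSE)
      expression_dataset(mat, ann)
    })
  })
  names(datasets) <- rownames(counts)
  datasets <- Filter(Negate(is.null), datasets)
  if (!length(datasets)) stop("configuration produced no samples")

  gt <- data.frame(
    gene = c(gene_names[!is.na(planted_of)], "ERBB2"),
    planted_contrast = c(planted_of[!is.na(planted_of)], "ordinal"),
    delta = c(vapply(planted_of[!is.na(planted_of)],
                     function(k) planted[[k]]$delta, 0), NA_real_),
    stringsAsFactors = FALSE)
  rownames(gt) <- NULL
  structure(list(datasets = datasets, ground_truth = gt, config = config),
            class = "SyntheticCohorts")
}

#' @export
print.SyntheticCohorts <- function(x, ...) {
  ns <- vapply(x$datasets, function(d) nrow(d$samples), 0L)
  cat(sprintf("SyntheticCohorts: %d cohort(s), %d samples, %d genes (%d planted)\n",
              length(x$datasets), sum(ns), length(x$datasets[[1]]$genes),
              sum(x$ground_truth$planted_contrast != "ordinal")))
  invisible(x)
}

#' Write synthetic cohorts to disk
#'
#' One matrix + annotation TSV pair per cohort (the [read_expression_dataset()]
#' format) plus a `ground_truth.tsv` sidecar (gene, planted_contrast, delta).
#'
#' @param cohorts A `SyntheticCohorts` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_synthetic_cohorts <- function(cohorts, dir) {
  stopifnot(inherits(cohorts, "SyntheticCohorts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- unlist(lapply(names(cohorts$datasets), function(co) {
    write_expression_dataset(
      cohorts$datasets[[co]],
      file.path(dir, paste0(co, "_expression.tsv")),
      file.path(dir, paste0(co, "_annotations.tsv")))
  }))
  gt_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(cohorts$ground_truth, gt_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, gt_path))
}
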