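# Data model and I/O for annotated expression cohorts.
#
# An ExpressionDataset couples a genes x samples matrix of log2 expression
# with per-sample clinical annotations (HER2 IHC score, ISH amplification,
# hormone-receptor status, PAM50 subtype, ...). All downstream stages
# (screening, signature fitting, scoring, evaluation) consume this container.

ANNOTATION_COLUMNS <- c("sample_id", "cohort", "ihc_score", "ish_amplified",
                        "hr_status", "pam50", "grade", "size_class",
                        "age_years")

IHC_LEVELS  <- c("0", "1+", "2+", "3+")
ISH_LEVELS  <- c("amplified", "not_amplified", "unknown")
HR_LEVELS   <- c("positive", "negative", "unknown")
PAM50_LEVELS <- c("LumA", "LumB", "HER2E", "Basal", "Normal",
                  "Undetermined", "unknown")
HER2_GROUPS <- c("zero", "low", "positive")

#' Construct an annotated expression dataset
#'
#' Couples a genes-by-samples matrix of log2-scale expression values with a
#' per-sample annotation table. Samples must appear in the same order in the
#' matrix columns and the annotation rows.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = unique gene
#'   symbols), samples in columns (colnames = sample ids). Values must be
#'   finite: missing expression is rejected, not imputed.
#' @param annotations `data.frame` with one row per sample. Must contain at
#'   least `sample_id`, `cohort` and `ihc_score`; the remaining annotation
#'   columns (`ish_amplified`, `hr_status`, `pam50`, `grade`, `size_class`,
#'   `age_years`) are filled with `"unknown"`/`NA` when absent.
#' @param scale_note Declared unit tag; only `"log2"` is accepted.
#'
#' @return An object of class `ExpressionDataset` with elements `genes`,
#'   `samples` (annotation `data.frame`), `matrix` and `scale_note`.
#' @export
expression_dataset <- function(matrix, annotations, scale_note = "log2") {
  if (!identical(scale_note, "log2"))
    stop("expression must be declared log2 scale (scale_note = \"log2\")")
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("matrix needs gene rownames and sample colnames")
  dup <- unique(rownames(matrix)[duplicated(rownames(matrix))])
  if (length(dup))
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "))
  if (any(!is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(matrix)[bad[1L]], colnames(matrix)[bad[2L]]))
  }
  annotations <- normalize_annotations(annotations)
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample_id in annotations")
  if (!identical(colnames(matrix), annotations$sample_id))
    stop("matrix columns and annotation rows must match in order")
  structure(
    list(genes = rownames(matrix), samples = annotations,
         matrix = matrix, scale_note = "log2"),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (cohort%s: %s)\n",
              length(x$genes), nrow(x$samples),
              if (length(unique(x$samples$cohort)) > 1) "s" else "",
              paste(unique(x$samples$cohort), collapse = ", ")))
  tab <- table(factor(x$samples$ihc_score, levels = IHC_LEVELS))
  cat("HER2 IHC: ", paste(sprintf("%s=%d", names(tab), tab), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' @keywords internal
#' @noRd
normalize_annotations <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "ihc_score")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("ish_amplified", "hr_status", "pam50")) {
    if (is.null(ann[[col]])) ann[[col]] <- "unknown"
    v <- as.character(ann[[col]])
    v[is.na(v) | v == ""] <- "unknown"
    ann[[col]] <- v
  }
  for (col in c("grade", "size_class")) {
    if (is.null(ann[[col]])) ann[[col]] <- NA_character_
    v <- as.character(ann[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    ann[[col]] <- v
  }
  if (is.null(ann[["age_years"]])) ann[["age_years"]] <- NA_real_
  ann$age_years <- suppressWarnings(as.numeric(ann$age_years))
  ann$sample_id <- as.character(ann$sample_id)
  ann$cohort <- as.character(ann$cohort)
  ann$ihc_score <- normalize_ihc(ann$ihc_score)
  bad <- setdiff(unique(ann$ish_amplified), ISH_LEVELS)
  if (length(bad))
    stop("unrecognized ish_amplified value(s): ", paste(bad, collapse = ", "),
         " (accepted: ", paste(ISH_LEVELS, collapse = ", "), ")")
  bad <- setdiff(unique(ann$hr_status), HR_LEVELS)
  if (length(bad))
    stop("unrecognized hr_status value(s): ", paste(bad, collapse = ", "))
  ann[, ANNOTATION_COLUMNS]
}

# Accepts "0","1+","2+","3+"; bare "1","2","3" are tolerated aliases for the
# "+" spellings (public annotation files vary) and trigger one warning.
#' @keywords internal
#' @noRd
normalize_ihc <- function(x) {
  x <- trimws(as.character(x))
  aliased <- x %in% c("1", "2", "3")
  if (any(aliased)) {
    warning(sprintf("%d IHC score(s) given as bare '1'/'2'/'3'; interpreted as '1+'/'2+'/'3+'",
                    sum(aliased)))
    x[aliased] <- paste0(x[aliased], "+")
  }
  bad <- setdiff(unique(x[!is.na(x)]), IHC_LEVELS)
  if (length(bad) || anyNA(x))
    stop("unrecognized HER2 IHC score token(s): ",
         paste(unique(c(bad, if (anyNA(x)) "<missing>")), collapse = ", "),
         ". Accepted spellings: 0, 1+, 2+, 3+ (and aliases 1, 2, 3).")
  x
}

#' Map HER2 IHC scores to the zero / low / positive grouping
#'
#' HER2-low is defined as IHC 1+, or IHC 2+ without ISH amplification; IHC 0
#' is HER2-zero; IHC 3+, or IHC 2+ with ISH amplification, is HER2-positive.
#' IHC 2+ with unknown ISH status maps to HER2-low (amplification among 2+
#' is uncommon and unresolved 2+ cases are conventionally pooled with low);
#' this choice is controlled by `unknown_ish_2plus`.
#'
#' @param ihc_score Character vector of IHC scores (`"0"`, `"1+"`, `"2+"`,
#'   `"3+"`; bare `"1"`,`"2"`,`"3"` accepted with a warning).
#' @param ish_amplified Character vector (`"amplified"`, `"not_amplified"`,
#'   `"unknown"`); recycled if length 1. Only consulted for IHC 2+; an
#'   `"amplified"` flag on any other score is ignored with a warning.
#' @param unknown_ish_2plus Group assigned to IHC 2+ with unknown ISH:
#'   `"low"` (default) or `"positive"`.
#'
#' @return Factor with levels `zero`, `low`, `positive`, one per input score.
#' @examples
#' classify_her2_group(c("0", "1+", "2+", "3+"))
#' classify_her2_group("2+", "amplified")
#' @export
classify_her2_group <- function(ihc_score, ish_amplified = "unknown",
                                unknown_ish_2plus = c("low", "positive")) {
  unknown_ish_2plus <- match.arg(unknown_ish_2plus)
  ihc <- normalize_ihc(ihc_score)
  ish <- rep_len(as.character(ish_amplified), length(ihc))
  bad <- setdiff(unique(ish), ISH_LEVELS)
  if (length(bad))
    stop("unrecognized ish_amplified value(s): ", paste(bad, collapse = ", "))
  stray <- ish == "amplified" & ihc != "2+"
  if (any(stray))
    warning(sprintf("ish_amplified = 'amplified' ignored for %d non-2+ sample(s)",
                    sum(stray)))
  grp <- ifelse(ihc == "0", "zero",
         ifelse(ihc == "1+", "low",
         ifelse(ihc == "3+", "positive",
         ifelse(ish == "amplified", "positive",
         ifelse(ish == "unknown", unknown_ish_2plus, "low")))))
  factor(grp, levels = HER2_GROUPS)
}

#' Read an expression matrix and annotation file into an ExpressionDataset
#'
#' The matrix file is genes-in-rows TSV/CSV (first column gene symbol, header
#' row of sample ids); the annotation file has one row per sample. Samples are
#' intersected and reordered to match; unmatched samples on either side are
#' dropped with a message. Missing or non-numeric expression cells are
#' rejected with their location.
#'
#' @param matrix_path,annotation_path Paths to delimited files; `.csv` is
#'   comma-separated, anything else tab-separated.
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(matrix_path, annotation_path) {
  mat_raw <- read_delim_auto(matrix_path)
  ann <- read_delim_auto(annotation_path)
  genes <- as.character(mat_raw[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbols in ", matrix_path, ": ",
         paste(dup, collapse = ", "))
  vals <- mat_raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(as.character(vals[[j]])))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing expression value at row %d (gene '%s'), column '%s'",
                   bad[1L], genes[bad[1L]], names(vals)[j]))
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes
  ann <- normalize_annotations(ann)
  common <- intersect(colnames(mat), ann$sample_id)
  if (!length(common))
    stop("no overlapping samples between matrix and annotation files")
  dropped <- (ncol(mat) - length(common)) + (nrow(ann) - length(common))
  if (dropped > 0)
    message(sprintf("read_expression_dataset: dropped %d unmatched sample(s) (%d matrix-only, %d annotation-only)",
                    dropped, ncol(mat) - length(common),
                    nrow(ann) - length(common)))
  mat <- mat[, common, drop = FALSE]
  ann <- ann[match(common, ann$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  expression_dataset(mat, ann)
}

#' Write an ExpressionDataset to delimited files
#'
#' Inverse of [read_expression_dataset()]: full-precision expression values,
#' so a write/read round trip reproduces the matrix bit-identically.
#'
#' @param dataset An `ExpressionDataset`.
#' @param matrix_path,annotation_path Output paths (`.csv` comma, else tab).
#' @return Invisibly, the two paths.
#' @export
write_expression_dataset <- function(dataset, matrix_path, annotation_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  mat_df <- data.frame(gene = dataset$genes,
                       apply(dataset$matrix, 2, function(col)
                         formatC(col, digits = 17, format = "g")),
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mat_df, matrix_path, sep = sep(matrix_path),
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples, annotation_path,
                     sep = sep(annotation_path), quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(matrix_path, annotation_path))
}

#' @keywords internal
#' @noRd
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "",
                    colClasses = "character")
}

#' Summarize cohort composition and HER2-group cross-tabulations
#'
#' Builds per-cohort and pooled count/percentage tables for every annotation
#' variable (missing values reported as their own level), plus
#' cross-tabulations of the HER2 zero/low/positive grouping against
#' hormone-receptor status, PAM50 subtype, grade and tumor size. Percentages
#' are computed on the column total and rounded half-up to integers, the
#' convention of clinical characteristics tables.
#'
#' @param datasets A single `ExpressionDataset`, a list of them, or a bare
#'   annotation `data.frame` (or list of such).
#' @param unknown_ish_2plus Passed to [classify_her2_group()].
#' @return An object of class `CohortSummary`: a list with `by_cohort` and
#'   `pooled` per-variable count tables, `her2_crosstab` (HER2 group x
#'   clinical variable counts and percents), `her2_group_counts`, and `n`.
#' @export
cohort_summary <- function(datasets, unknown_ish_2plus = "low") {
  ann <- gather_annotations(datasets)
  ann$her2_group <- as.character(
    classify_her2_group(ann$ihc_score, ann$ish_amplified,
                        unknown_ish_2plus = unknown_ish_2plus))
  cohorts <- unique(ann$cohort)
  vars <- c("ihc_score", "her2_group", "hr_status", "pam50", "grade",
            "size_class")
  levs <- list(ihc_score = IHC_LEVELS, her2_group = HER2_GROUPS,
               hr_status = HR_LEVELS, pam50 = PAM50_LEVELS,
               grade = NULL, size_class = NULL)
  count_table <- function(sub) {
    out <- list()
    for (v in vars) {
      x <- sub[[v]]
      x[is.na(x)] <- "missing"
      x[x == "unknown"] <- "missing"
      lv <- levs[[v]]
      lv <- unique(c(setdiff(lv, "unknown"), setdiff(unique(x), "missing"),
                     if (any(x == "missing")) "missing"))
      cnt <- as.integer(table(factor(x, levels = lv)))
      out[[v]] <- data.frame(level = lv, n = cnt,
                             pct = percent_half_up(cnt, nrow(sub)),
                             stringsAsFactors = FALSE)
    }
    out
  }
  by_cohort <- lapply(cohorts, function(co)
    count_table(ann[ann$cohort == co, , drop = FALSE]))
  names(by_cohort) <- cohorts
  pooled <- count_table(ann)

  cross_vars <- c("hr_status", "pam50", "grade", "size_class")
  her2_crosstab <- lapply(cross_vars, function(v) {
    x <- ann[[v]]
    x[is.na(x) | x == "unknown"] <- "missing"
    tab <- table(level = x, her2_group = factor(ann$her2_group,
                                                levels = HER2_GROUPS))
    cnt <- as.data.frame.matrix(tab)
    pct <- as.data.frame(lapply(seq_len(ncol(cnt)), function(j)
      percent_half_up(cnt[[j]], sum(cnt[[j]]))))
    dimnames(pct) <- dimnames(cnt)
    list(counts = cnt, percent_of_group = pct)
  })
  names(her2_crosstab) <- cross_vars

  structure(list(
    n = nrow(ann),
    n_by_cohort = stats::setNames(as.integer(table(ann$cohort)[cohorts]), cohorts),
    her2_group_counts = stats::setNames(
      as.integer(table(factor(ann$her2_group, levels = HER2_GROUPS))),
      HER2_GROUPS),
    by_cohort = by_cohort, pooled = pooled,
    her2_crosstab = her2_crosstab), class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("CohortSummary: %d samples in %d cohort(s)\n", x$n,
              length(x$by_cohort)))
  g <- x$her2_group_counts
  p <- percent_half_up(g, x$n)
  cat(sprintf("HER2 groups: zero %d (%d%%), low %d (%d%%), positive %d (%d%%)\n",
              g[["zero"]], p[1L], g[["low"]], p[2L], g[["positive"]], p[3L]))
  invisible(x)
}

#' Export a CohortSummary as TSV and/or JSON
#'
#' @param summary A `CohortSummary`.
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_cohort_summary <- function(summary, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(summary, "CohortSummary"))
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(names(summary$pooled), function(v)
      cbind(variable = v, summary$pooled[[v]])))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) write_json_exact(unclass(summary), json_path)
  invisible(c(tsv_path, json_path))
}

#' @keywords internal
#' @noRd
gather_annotations <- function(datasets) {
  if (inherits(datasets, "ExpressionDataset")) datasets <- list(datasets)
  if (is.data.frame(datasets)) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one dataset is required")
  ann <- do.call(rbind, lapply(datasets, function(d) {
    if (inherits(d, "ExpressionDataset")) d$samples
    else normalize_annotations(d)
  }))
  rownames(ann) <- NULL
  ann
}
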