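# Config-driven orchestration of the full workflow:
# discover (screen + Venn per discovery cohort) -> merge -> fit PC1 signature
# -> score every cohort -> evaluate (KW, post hoc, ROC/AUC, Youden cutoff,
# partial correlations) -> report.

#' Pipeline configuration
#'
#' @param discovery Named list of discovery inputs: each an
#'   [expression_dataset()] or a `list(matrix =, annotations =)` pair of file
#'   paths.
#' @param confirmatory Like `discovery`, for cohorts that are only scored and
#'   evaluated (may be empty).
#' @param fc_threshold,alpha Screening thresholds (see
#'   [select_contrast_degs()]).
#' @param posthoc_adjust `"none"` or `"bonferroni"` for the post hoc pairwise
#'   tests.
#' @param rp_edge_threshold Partial-correlation edge reporting bar.
#' @param fit_cohort Name of the discovery dataset the PCA is fitted on;
#'   `NULL` picks the first discovery cohort carrying all four IHC
#'   categories (falling back to the first cohort).
#' @param standardization_mode `"per-dataset"` (default) or `"train-params"`
#'   for scoring.
#' @param venn_mode `"hierarchical"` or `"exclusive"` (see
#'   [venn_specific_genes()]).
#' @param categories Specific cells feeding the signature (default 1+, 2+,
#'   low).
#' @param subset Optional named list of annotation filters applied to the
#'   evaluation stage only, e.g. `list(hr_status = "positive")`.
#' @param benchmark_gene Single-gene AUC benchmark (default `"ERBB2"`;
#'   skipped with a note when absent).
#' @param missing_genes Missing-signature-gene policy when scoring
#'   (`"error"` or `"drop"`).
#' @param seed Integer seed recorded in the report (the pipeline itself is
#'   deterministic; the seed feeds any upstream simulation).
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(discovery, confirmatory = list(),
                            fc_threshold = 1, alpha = 0.05,
                            posthoc_adjust = c("none", "bonferroni"),
                            rp_edge_threshold = 0.30,
                            fit_cohort = NULL,
                            standardization_mode = c("per-dataset", "train-params"),
                            venn_mode = c("hierarchical", "exclusive"),
                            categories = c("1+", "2+", "low"),
                            subset = NULL,
                            benchmark_gene = "ERBB2",
                            missing_genes = c("error", "drop"),
                            seed = 1L, output_dir = NULL) {
  stopifnot(length(discovery) >= 1,
            is_scalar_number(fc_threshold) || is.infinite(fc_threshold),
            is_scalar_number(alpha), alpha > 0, alpha < 1,
            is_scalar_number(rp_edge_threshold), rp_edge_threshold >= 0)
  structure(list(
    discovery = discovery, confirmatory = confirmatory,
    fc_threshold = fc_threshold, alpha = alpha,
    posthoc_adjust = match.arg(posthoc_adjust),
    rp_edge_threshold = rp_edge_threshold,
    fit_cohort = fit_cohort,
    standardization_mode = match.arg(standardization_mode),
    venn_mode = match.arg(venn_mode),
    categories = categories, subset = subset,
    benchmark_gene = benchmark_gene,
    missing_genes = match.arg(missing_genes),
    seed = as.integer(seed), output_dir = output_dir),
    class = "PipelineConfig")
}

#' @keywords internal
#' @noRd
load_input <- function(x, label) {
  if (inherits(x, "ExpressionDataset")) return(x)
  if (is.list(x) && !is.null(x$matrix) && !is.null(x$annotations))
    return(read_expression_dataset(x$matrix, x$annotations))
  stop("input '", label,
       "' must be an ExpressionDataset or list(matrix=, annotations=) paths")
}

#' @keywords internal
#' @noRd
apply_subset <- function(dataset, subset) {
  if (is.null(subset) || !length(subset)) return(dataset)
  keep <- rep(TRUE, nrow(dataset$samples))
  for (col in names(subset))
    keep <- keep & dataset$samples[[col]] %in% subset[[col]]
  if (!any(keep)) stop("subset filter removed every sample")
  expression_dataset(dataset$matrix[, keep, drop = FALSE],
                     dataset$samples[keep, , drop = FALSE])
}

#' Run the full discovery-to-evaluation pipeline
#'
#' Executes, in order: per-discovery-cohort one-vs-rest screening of the five
#' HER2 contrasts; Venn assignment of significant genes to specific cells;
#' cross-cohort merge of the 1+/2+/low cells; PC1 signature fit on the fit
#' cohort; scoring of every cohort; and per-cohort evaluation (Kruskal-Wallis
#' over IHC categories, post hoc HER2-low vs zero and vs positive rank-sum
#' tests, ROC AUC of low vs others with DeLong CI, Youden cutoff, per-category
#' score summaries, single-gene benchmark), plus the partial-correlation
#' network of the signature genes on the fit cohort. Any stage error aborts
#' with the stage name. When `config$output_dir` is set, all artifacts are
#' written there via [write_report()].
#'
#' @param config A [pipeline_config()].
#' @return A `PipelineResult` bundle: `model`, `selection`, `screens`,
#'   `venn`, `scores` (per cohort), `evaluation` (per cohort), `network`,
#'   `report` (plain-list summary serialized as report.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  discovery <- stage("load-discovery", {
    ds <- lapply(seq_along(config$discovery), function(i)
      load_input(config$discovery[[i]],
                 names(config$discovery)[i] %||% paste0("discovery", i)))
    names(ds) <- names(config$discovery) %||%
      paste0("discovery", seq_along(ds))
    if (is.null(names(config$discovery)))
      names(ds) <- vapply(ds, function(d) d$samples$cohort[1], "")
    ds
  })
  confirmatory <- stage("load-confirmatory", {
    ds <- lapply(seq_along(config$confirmatory), function(i)
      load_input(config$confirmatory[[i]], paste0("confirmatory", i)))
    if (length(ds))
      names(ds) <- names(config$confirmatory) %||%
        vapply(ds, function(d) d$samples$cohort[1], "")
    ds
  })

  screens <- stage("screen", lapply(discovery, screen_dataset,
                                    fc_threshold = config$fc_threshold,
                                    alpha = config$alpha))
  venns <- stage("venn", lapply(screens, venn_specific_genes,
                                mode = config$venn_mode))
  selection <- stage("merge", merge_discovery(venns,
                                              categories = config$categories))
  if (nrow(selection) < 2)
    stop("pipeline stage 'merge' failed: fewer than 2 signature genes selected; ",
         "relax thresholds or check the discovery data", call. = FALSE)

  fit_name <- config$fit_cohort %||% {
    full <- vapply(discovery, function(d)
      all(IHC_LEVELS %in% d$samples$ihc_score), TRUE)
    if (any(full)) names(discovery)[which(full)[1]] else names(discovery)[1]
  }
  if (!fit_name %in% names(discovery))
    stop("pipeline stage 'fit' failed: fit_cohort '", fit_name,
         "' is not a discovery dataset", call. = FALSE)
  fit_ds <- discovery[[fit_name]]
  genes_avail <- intersect(selection$gene, fit_ds$genes)
  model <- stage("fit", fit_signature(fit_ds, genes_avail))

  all_ds <- c(discovery, confirmatory)
  scores <- stage("score", lapply(all_ds, function(d)
    score_samples(model, d, standardization_mode = config$standardization_mode,
                  missing_genes = config$missing_genes)))

  evaluation <- stage("evaluate", lapply(names(all_ds), function(nm) {
    d <- apply_subset(all_ds[[nm]], config$subset)
    sc <- score_samples(model, d,
                        standardization_mode = config$standardization_mode,
                        missing_genes = config$missing_genes)
    grp <- classify_her2_group(d$samples$ihc_score, d$samples$ish_amplified)
    cats_present <- length(unique(d$samples$ihc_score)) >= 2
    kw <- if (cats_present)
      suppressWarnings(kruskal_wallis(sc$score, d$samples$ihc_score))
    else NULL
    posthoc <- suppressWarnings(
      pairwise_posthoc(sc$score, as.character(grp),
                       adjust = config$posthoc_adjust))
    roc <- cutoff <- bench <- NULL
    if (any(grp == "low") && any(grp != "low")) {
      roc <- roc_auc(sc$score, grp == "low")
      cutoff <- youden_cutoff(sc$score, grp == "low")
      if (config$benchmark_gene %in% d$genes)
        bench <- compare_signature_vs_gene(
          model, d, benchmark_gene = config$benchmark_gene,
          positive = "low",
          standardization_mode = config$standardization_mode)
    }
    list(cohort = nm, n = nrow(d$samples), kw = kw, posthoc = posthoc,
         roc_low_vs_others = roc, youden = cutoff, benchmark = bench,
         score_summary = score_summary_by_category(sc$score,
                                                   d$samples$ihc_score))
  }))
  names(evaluation) <- names(all_ds)

  network <- stage("network", {
    d <- fit_ds
    if (nrow(d$samples) > length(model$genes) + 1)
      partial_correlation_matrix(d, model$genes,
                                 edge_threshold = config$rp_edge_threshold)
    else NULL
  })

  report <- build_report(config, discovery, confirmatory, venns, selection,
                         model, evaluation, network)
  bundle <- structure(list(
    config = config, model = model, selection = selection,
    screens = screens, venn = venns, scores = scores,
    evaluation = evaluation, network = network, report = report),
    class = "PipelineResult")
  if (!is.null(config$output_dir)) write_report(bundle, config$output_dir)
  bundle
}

#' @keywords internal
#' @noRd
build_report <- function(config, discovery, confirmatory, venns, selection,
                         model, evaluation, network) {
  venn_counts <- lapply(venns, function(v)
    lapply(v$specific, length))
  eval_json <- lapply(evaluation, function(e) {
    list(cohort = e$cohort, n = e$n,
         kw_statistic = if (!is.null(e$kw)) e$kw$statistic,
         kw_p = if (!is.null(e$kw)) e$kw$p,
         posthoc = as.list(e$posthoc),
         auc = if (!is.null(e$roc_low_vs_others)) e$roc_low_vs_others$auc,
         auc_ci = if (!is.null(e$roc_low_vs_others))
           c(e$roc_low_vs_others$ci_low, e$roc_low_vs_others$ci_high),
         auc_degenerate = if (!is.null(e$roc_low_vs_others))
           e$roc_low_vs_others$auc %in% c(0, 1),
         youden_cutoff = if (!is.null(e$youden)) e$youden$cutoff,
         youden_j = if (!is.null(e$youden)) e$youden$youden_j,
         benchmark_auc = if (!is.null(e$benchmark)) e$benchmark$benchmark$auc,
         auc_difference = if (!is.null(e$benchmark)) e$benchmark$auc_difference,
         score_summary = e$score_summary)
  })
  list(
    tool = "her2lowsig",
    seed = config$seed,
    settings = list(
      fc_threshold = config$fc_threshold, alpha = config$alpha,
      bonferroni_family = "flagged-genes-per-contrast",
      posthoc_adjust = config$posthoc_adjust,
      rp_edge_threshold = config$rp_edge_threshold,
      standardization_mode = config$standardization_mode,
      venn_mode = config$venn_mode,
      categories = config$categories,
      fit_cohort = model$fit_cohort,
      subset = config$subset,
      missing_genes = config$missing_genes),
    cohorts = list(
      discovery = lapply(discovery, function(d) nrow(d$samples)),
      confirmatory = lapply(confirmatory, function(d) nrow(d$samples)),
      summary = unclass(cohort_summary(c(discovery, confirmatory)))[
        c("n", "n_by_cohort", "her2_group_counts")]),
    venn_specific_counts = venn_counts,
    signature = list(
      n_genes = length(model$genes), genes = model$genes,
      per_category = as.list(table(selection$category)),
      explained_share = model$explained_share,
      orientation = model$orientation),
    evaluation = eval_json,
    network_edges = if (!is.null(network)) network$edges else NULL)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits `model.json` (the serialized signature), `scores_<cohort>.tsv`,
#' `selection.tsv` (merged specific genes), `report.json` (machine-readable,
#' deterministic: no timestamps) and `report.md` (human-readable summary with
#' cohort counts, Venn-specific counts, per-category score five-number
#' summaries and the AUC comparison line). An empty confirmatory list is
#' noted rather than omitted silently; a degenerate AUC is flagged.
#'
#' @param bundle A `PipelineResult` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "PipelineResult"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character()
  p <- file.path(dir, "model.json"); write_signature_model(bundle$model, p)
  paths <- c(paths, p)
  for (nm in names(bundle$scores)) {
    p <- file.path(dir, paste0("scores_", nm, ".tsv"))
    utils::write.table(bundle$scores[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "selection.tsv")
  utils::write.table(as.data.frame(bundle$selection), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "report.json"); write_json_exact(bundle$report, p)
  paths <- c(paths, p)
  p <- file.path(dir, "report.md")
  writeLines(render_report_md(bundle), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' @keywords internal
#' @noRd
render_report_md <- function(bundle) {
  rep <- bundle$report
  lines <- c("# HER2-low signature pipeline report", "",
             sprintf("Seed: %d", rep$seed), "",
             "## Cohorts")
  cs <- rep$cohorts$summary
  lines <- c(lines,
             sprintf("Total samples: %d", cs$n),
             sprintf("- %s: n = %d", names(cs$n_by_cohort), cs$n_by_cohort),
             sprintf("HER2 groups (pooled): zero %d, low %d, positive %d",
                     cs$her2_group_counts[["zero"]],
                     cs$her2_group_counts[["low"]],
                     cs$her2_group_counts[["positive"]]), "",
             "## Category-specific genes (Venn cells)")
  for (nm in names(rep$venn_specific_counts)) {
    vc <- rep$venn_specific_counts[[nm]]
    lines <- c(lines, sprintf("- %s: %s", nm,
                              paste(sprintf("%s=%d", names(vc),
                                            unlist(vc)), collapse = ", ")))
  }
  lines <- c(lines, "",
             sprintf("## Signature: %d genes, PC1 explains %.1f%%",
                     rep$signature$n_genes,
                     100 * rep$signature$explained_share), "")
  if (!length(bundle$config$confirmatory))
    lines <- c(lines, "_No confirmatory cohorts were provided._", "")
  for (e in rep$evaluation) {
    lines <- c(lines, sprintf("## Evaluation: %s (n = %d)", e$cohort, e$n))
    if (!is.null(e$kw_p))
      lines <- c(lines, sprintf("Kruskal-Wallis across IHC categories: H = %.3f, p = %.3g",
                                e$kw_statistic, e$kw_p))
    if (length(e$posthoc))
      lines <- c(lines, sprintf("Post hoc %s: p = %.3g", names(e$posthoc),
                                unlist(e$posthoc)))
    if (!is.null(e$auc)) {
      lines <- c(lines, sprintf("AUC (low vs others) = %.3f (95%% CI %.3f-%.3f)%s",
                                e$auc, e$auc_ci[1], e$auc_ci[2],
                                if (isTRUE(e$auc_degenerate))
                                  " [degenerate AUC; CI clipped]" else ""))
      if (!is.null(e$benchmark_auc))
        lines <- c(lines, sprintf("Benchmark gene AUC = %.3f (signature - benchmark = %+.3f)",
                                  e$benchmark_auc, e$auc_difference))
      lines <- c(lines, sprintf("Youden cutoff = %.4f (J = %.3f)",
                                e$youden_cutoff, e$youden_j))
    }
    ss <- e$score_summary
    lines <- c(lines, "", "category | n | min | q1 | median | q3 | max",
               "---|---|---|---|---|---|---",
               sprintf("%s | %d | %.3f | %.3f | %.3f | %.3f | %.3f",
                       ss$category, ss$n, ss$min, ss$q1, ss$median, ss$q3,
                       ss$max), "")
  }
  lines
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config cfg.json --out dir` (generate synthetic
#' cohorts and write them as TSV) and `run-all --config cfg.json --out dir`
#' (full pipeline on file inputs). The JSON config mirrors
#' [pipeline_config()] / [synthetic_config()] fields. Exit codes: 0 ok,
#' 1 user error, 2 internal error.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: her2lowsig <simulate|run-all> --config cfg.json --out dir")
    invisible(1L)
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) != 1 || i == length(args)) return(NULL)
    args[i + 1]
  }
  cfg_path <- opt("--config"); out <- opt("--out")
  if (is.null(cfg_path) || is.null(out) ||
      !cmd %in% c("simulate", "run-all")) return(usage())
  code <- tryCatch({
    cfg <- jsonlite::fromJSON(cfg_path, simplifyVector = TRUE)
    if (cmd == "simulate") {
      counts <- do.call(rbind, cfg$n_per_category_per_cohort)
      sc <- synthetic_config(
        n_per_category_per_cohort = counts,
        n_background_genes = cfg$n_background_genes %||% 1000,
        noise_sd = cfg$noise_sd %||% 0.5,
        cohort_offset_sd = cfg$cohort_offset_sd %||% 0.25,
        seed = cfg$seed %||% 1L)
      write_synthetic_cohorts(generate_cohorts(sc), out)
    } else {
      as_inputs <- function(x) lapply(seq_len(nrow(x)), function(i)
        list(matrix = x$matrix[i], annotations = x$annotations[i]))
      disc <- as_inputs(as.data.frame(cfg$discovery))
      conf <- if (!is.null(cfg$confirmatory))
        as_inputs(as.data.frame(cfg$confirmatory)) else list()
      pc <- pipeline_config(
        discovery = disc, confirmatory = conf,
        fc_threshold = cfg$fc_threshold %||% 1,
        alpha = cfg$alpha %||% 0.05,
        seed = cfg$seed %||% 1L, output_dir = out)
      run_pipeline(pc)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^pipeline stage", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}
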