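#' Run the full simulate -> quantify -> qPCR -> biomarker pipeline
#'
#' Orchestrates one reproducible analysis on a simulated cohort: cohort
#' generation, library-size normalization, group-wise presence filtering,
#' circular-to-linear ratio quantification, qPCR circular-fraction
#' differential testing with two-stage FDR, the circular-to-linear score,
#' ROC/AUC, MRC/MIRS/splicing correlations, and a run manifest. Identical
#' config + seed reproduce byte-identical outputs.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory; `NULL` skips writing and returns
#'   results only.
#' @param n_qpcr_targets number of genes carried into the qPCR arm (all
#'   planted genes plus the first null genes up to this count; default 9).
#' @param q FDR level for the differential analysis (default 0.01).
#' @param min_presence,presence_mode forwarded to [presence_filter()].
#' @param score_features optional explicit feature set for the score; by
#'   default the significantly modulated circular fractions are used.
#' @param verbose print one line per stage.
#' @return list of class `circlin_run`: simulated inputs, stage outputs
#'   (`filtered`, `ratios`, `differential`, `score`, `roc`,
#'   `correlations`, `mirs`, `splicing`), `counts` bookkeeping, and
#'   `manifest`; plus `paths` when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_qpcr_targets = 9L,
                         q = 0.01, min_presence = 0.7,
                         presence_mode = "either",
                         score_features = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "circlin_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- simulate_cohort(config)
  say("simulate: %d events x %d samples", nrow(cohort$backsplice$events),
      ncol(cohort$backsplice$counts))

  norm <- normalize_per_million(cohort$backsplice)
  norm_linear <- cohort$linear
  norm_linear$count <- norm_linear$count * 1e6 /
    cohort$truth$lib_sizes[norm_linear$sample_id]
  filtered <- presence_filter(norm, cohort$metadata,
                              min_fraction = min_presence,
                              mode = presence_mode)
  say("presence filter: %d of %d events kept", nrow(filtered$events),
      nrow(norm$events))
  ratios <- ratio_matrix(filtered, norm_linear, cohort$metadata)

  gene_ids <- names(cohort$truth$expr)
  tp <- cohort$truth$true_positive_ids
  targets <- head(unique(c(tp, gene_ids)), min(n_qpcr_targets,
                                               length(gene_ids)))
  ct <- simulate_ct_matrix(config, cohort$truth, targets)
  fractions <- circ_fraction(ct, targets)
  fmat <- fraction_matrix(fractions)
  differential <- differential_analysis(fmat, cohort$metadata, q = q)
  sig <- differential$feature_id[differential$q_flag]
  say("differential: %d of %d fractions significant at q = %g",
      length(sig), nrow(differential), q)

  feats <- score_features %||% sig
  score <- NULL; roc <- NULL; mirs <- NULL
  correlations <- tibble::tibble()
  splicing <- simulate_splicing_table(config, cohort$truth)
  exclusion <- exon_exclusion_percent(splicing)
  if (length(feats) > 0) {
    score <- circ_lin_score(fmat, feats, cohort$metadata)
    roc <- roc_auc(score$scores, cohort$metadata)
    mirs <- mirs_group_compare(score$scores, cohort$metadata)
    cov <- dplyr::left_join(
      cohort$metadata[c("sample_id", "mrc_megascore")],
      tidyr::pivot_wider(exclusion[c("event_name", "sample_id", "percent")],
                         names_from = "event_name",
                         values_from = "percent"),
      by = "sample_id")
    sv <- setNames(score$scores$score, score$scores$sample_id)
    correlations <- correlate_with_covariates(sv, cov)
    say("biomarker: score AUC %.3f", roc$auc)
  } else {
    say("biomarker: no significant features; score not computed")
  }

  counts <- list(events_simulated = nrow(cohort$backsplice$events),
                 events_after_filter = nrow(filtered$events),
                 events_removed = nrow(cohort$backsplice$events) -
                   nrow(filtered$events),
                 features_tested = nrow(differential),
                 features_significant = length(sig))
  run <- structure(
    list(config = config, cohort = cohort, filtered = filtered,
         ratios = ratios, ct = ct, fractions = fractions,
         differential = differential, score = score, roc = roc,
         mirs = mirs, correlations = correlations, splicing = splicing,
         exclusion = exclusion, counts = counts),
    class = "circlin_run")

  if (!is.null(out_dir)) {
    run$paths <- write_run(run, out_dir)
  }
  run
}

fraction_matrix <- function(fractions) {
  wide <- tidyr::pivot_wider(
    fractions[c("target_id", "sample_id", "log2_fraction")],
    names_from = "sample_id", values_from = "log2_fraction")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$target_id
  m
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_junction_table(run$cohort$backsplice,
                       file.path(out_dir, "backsplice_counts.tsv"))
  write_circlin_tsv(run$cohort$linear,
                    file.path(out_dir, "linear_junctions.tsv"),
                    "linear_junctions")
  write_circlin_tsv(run$cohort$metadata, file.path(out_dir, "metadata.tsv"),
                    "metadata")
  write_circlin_tsv(run$ct, file.path(out_dir, "ct_matrix.tsv"), "ct")
  write_circlin_tsv(run$splicing, file.path(out_dir, "splicing.tsv"),
                    "splicing")
  results <- list(ratio_summary = run$ratios$summary,
                  differential = run$differential,
                  correlations = run$correlations)
  if (!is.null(run$score)) {
    results$score <- run$score$scores
    results$roc_curve <- run$roc$curve
  }
  manifest <- list(
    seed = run$config$seed,
    config = unclass(run$config),
    counts = run$counts,
    summary = list(
      score_auc = if (is.null(run$roc)) NULL else run$roc$auc,
      mirs_p = if (is.null(run$mirs)) NULL else run$mirs$p_value))
  paths <- write_results(results, out_dir, manifest = manifest)
  report_path <- file.path(out_dir, "report.md")
  writeLines(report(run), report_path)
  c(paths, report = report_path,
    backsplice = file.path(out_dir, "backsplice_counts.tsv"),
    linear = file.path(out_dir, "linear_junctions.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    ct = file.path(out_dir, "ct_matrix.tsv"),
    splicing = file.path(out_dir, "splicing.tsv"))
}

#' Human-readable run report
#'
#' Markdown summary of the quantities a cohort analysis reports: events
#' surviving the presence filter, the differential table with q-flags, the
#' circular-to-linear score and its AUC, and correlations with clinical
#' and splicing covariates.
#'
#' @param run a `circlin_run` from [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
report <- function(run) {
  stopifnot(inherits(run, "circlin_run"))
  cn <- run$counts
  lines <- c(
    "# circlin run report", "",
    sprintf("- seed: %d", run$config$seed),
    sprintf("- cohort: %d cases / %d controls", run$config$n_cases,
            run$config$n_controls),
    sprintf("- back-splice events simulated: %d", cn$events_simulated),
    sprintf("- events after presence filter: %d (removed %d)",
            cn$events_after_filter, cn$events_removed),
    sprintf("- circular fractions tested: %d; significant at q: %d",
            cn$features_tested, cn$features_significant), "")
  if (nrow(run$differential) > 0) {
    lines <- c(lines, "## Differential circular fractions", "",
               "| feature | test | p | q-flag | log2FC |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.3g | %s | %.2f |",
                       run$differential$feature_id,
                       run$differential$test_used,
                       run$differential$p_value,
                       ifelse(run$differential$q_flag, "yes", "no"),
                       run$differential$log2_fc_group), "")
  }
  if (is.null(run$score)) {
    lines <- c(lines, "no significant features; score not computed")
  } else {
    lines <- c(lines, "## Circular-to-linear score", "",
               sprintf("- features averaged: %s",
                       paste(run$score$feature_set, collapse = ", ")),
               sprintf("- ROC AUC (case vs control): %.3f", run$roc$auc),
               sprintf("- MIRS high (4-5) vs low (2-3): mean %.2f vs %.2f, p = %.3g",
                       run$mirs$mean_high, run$mirs$mean_low,
                       run$mirs$p_value), "")
    if (nrow(run$correlations) > 0) {
      lines <- c(lines, "## Score vs covariates", "",
                 "| covariate | r | p | n |", "|---|---|---|---|",
                 sprintf("| %s | %.3f | %.3g | %d |",
                         run$correlations$covariate, run$correlations$r,
                         run$correlations$p_value, run$correlations$n), "")
    }
  }
  lines
}

#' @export
print.circlin_run <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}
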