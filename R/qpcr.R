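#' Primer amplification efficiency from a dilution series
#'
#' Least-squares slope m of Ct against log10(dilution); the amplification
#' factor is `10^(-1/m)` (2.0 = perfect doubling per cycle). A slope of
#' -3.3219 therefore corresponds to efficiency 2.0, and -3.9 to about 1.8
#' (the usual flag level for an inefficient assay).
#'
#' @param dilution_log10 log10 template dilutions (>= 3 points).
#' @param ct corresponding Ct values.
#' @return list with `efficiency`, `slope`, `r_squared`, `valid` (FALSE
#'   when the slope is non-negative, i.e. Ct not decreasing with template).
#' @export
primer_efficiency <- function(dilution_log10, ct) {
  if (length(dilution_log10) != length(ct)) {
    abort_circlin("dilution and Ct vectors must have equal length")
  }
  if (length(ct) < 3) {
    abort_circlin("primer efficiency needs at least 3 dilution points")
  }
  fit <- stats::lm(ct ~ dilution_log10)
  m <- unname(coef(fit)[2])
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  if (!is.finite(m) || m >= 0) {
    return(list(efficiency = NA_real_, slope = m, r_squared = r2,
                valid = FALSE))
  }
  list(efficiency = 10^(-1 / m), slope = m, r_squared = r2, valid = TRUE)
}

# average technical replicates to one Ct per (target, isoform, sample)
average_replicates <- function(ct) {
  ct |>
    dplyr::group_by(.data$target_id, .data$isoform, .data$sample_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
}

#' Relative expression by the comparative Ct method (2^-ddCt)
#'
#' Per sample, `dCt = Ct_target - mean(reference Cts)` (replicates averaged
#' first); `ddCt = dCt - mean(dCt over control samples)` per target;
#' `rel_expr = 2^-ddCt`; `log2_fc = -ddCt`. Samples missing any reference
#' assay are excluded for all targets (with a message). The result is
#' invariant under any constant shift applied to all Cts of all samples.
#'
#' @param ct long Ct tibble (`target_id`, `isoform`, `sample_id`,
#'   `replicate`, `ct`).
#' @param targets target ids to quantify; each (target, isoform) pair with
#'   isoform `circular` or `linear` is treated as its own feature named
#'   `target@isoform`.
#' @param reference_ids reference assay target ids.
#' @param metadata sample metadata (`sample_id`, `group`).
#' @return tibble: `feature_id`, `target_id`, `isoform`, `sample_id`,
#'   `delta_ct`, `rel_expr`, `log2_fc`.
#' @export
relative_expression <- function(ct, targets, reference_ids, metadata) {
  assert_two_groups(metadata)
  avg <- average_replicates(ct)
  refs <- avg[avg$target_id %in% reference_ids &
                avg$isoform == "reference", , drop = FALSE]
  ref_mean <- refs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_ct = mean(.data$ct), n_ref = dplyr::n(),
                     .groups = "drop")
  complete <- ref_mean$sample_id[ref_mean$n_ref == length(reference_ids)]
  dropped <- setdiff(unique(avg$sample_id), complete)
  if (length(dropped) > 0) {
    message(sprintf("excluding %d sample(s) with incomplete references: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  tg <- avg[avg$target_id %in% targets & avg$isoform != "reference" &
              avg$sample_id %in% complete, , drop = FALSE]
  tg <- dplyr::left_join(tg, ref_mean[c("sample_id", "ref_ct")],
                         by = "sample_id")
  tg$delta_ct <- tg$ct - tg$ref_ct
  grp <- metadata$group[match(tg$sample_id, metadata$sample_id)]
  ctrl_mean <- tg[grp == "control", ] |>
    dplyr::group_by(.data$target_id, .data$isoform) |>
    dplyr::summarise(ctrl_dct = mean(.data$delta_ct), .groups = "drop")
  tg <- dplyr::left_join(tg, ctrl_mean, by = c("target_id", "isoform"))
  tg$log2_fc <- -(tg$delta_ct - tg$ctrl_dct)
  tg$rel_expr <- 2^tg$log2_fc
  tibble::tibble(
    feature_id = paste0(tg$target_id, "@", tg$isoform),
    target_id = tg$target_id, isoform = tg$isoform,
    sample_id = tg$sample_id, delta_ct = tg$delta_ct,
    rel_expr = tg$rel_expr, log2_fc = tg$log2_fc)
}

#' Circular fraction from raw Ct differences
#'
#' For each circular/linear pair, `dct = Ct_circ - Ct_lin` (replicates
#' averaged first) and `log2_fraction = -dct`, i.e. the log2
#' circular-to-linear ratio under the efficiency-2 assumption. No reference
#' normalization enters: both isoforms are measured in the same RNA, so
#' their raw Ct difference is internally controlled. Samples missing either
#' isoform yield no record.
#'
#' @param ct long Ct tibble.
#' @param circ_linear_pairs target ids having both a `circular` and a
#'   `linear` isoform record.
#' @return tibble: `target_id`, `sample_id`, `dct`, `log2_fraction`.
#' @export
circ_fraction <- function(ct, circ_linear_pairs) {
  avg <- average_replicates(ct)
  avg <- avg[avg$target_id %in% circ_linear_pairs &
               avg$isoform %in% c("circular", "linear"), , drop = FALSE]
  wide <- tidyr::pivot_wider(avg, names_from = "isoform",
                             values_from = "ct")
  if (!"circular" %in% names(wide)) wide$circular <- NA_real_
  if (!"linear" %in% names(wide)) wide$linear <- NA_real_
  wide <- wide[!is.na(wide$circular) & !is.na(wide$linear), , drop = FALSE]
  tibble::tibble(target_id = wide$target_id, sample_id = wide$sample_id,
                 dct = wide$circular - wide$linear,
                 log2_fraction = -(wide$circular - wide$linear))
}

#' Two-group test with a normality-gated policy
#'
#' Policy `auto`: when both groups have n >= 8 and both pass the
#' D'Agostino-Pearson omnibus test (p > `normality_alpha`), a two-tailed
#' two-sample Student t-test is used (Welch by `var_equal = FALSE`);
#' otherwise a two-tailed Mann-Whitney test (exact for small samples
#' without ties, normal approximation with tie correction otherwise).
#' Groups smaller than 8 always fall back to Mann-Whitney under `auto`,
#' since the normality test is not defined there. The group fold change is
#' the difference of group means, i.e. a log2 fold change when the inputs
#' are log2-scale (delta-Ct-derived) values.
#'
#' @param values_case,values_control numeric vectors (>= 2 each).
#' @param normality_alpha gate level for the normality test (default 0.05).
#' @param test_policy `"auto"`, `"t"`, or `"mann_whitney"`.
#' @param var_equal use the pooled-variance Student t-test (default TRUE).
#' @return list: `p_value`, `test_used`, `log2_fc_group`,
#'   `normality_p_case`, `normality_p_control`, `n_case`, `n_control`.
#' @export
group_test <- function(values_case, values_control, normality_alpha = 0.05,
                       test_policy = c("auto", "t", "mann_whitney"),
                       var_equal = TRUE) {
  test_policy <- match.arg(test_policy)
  x <- values_case[is.finite(values_case)]
  y <- values_control[is.finite(values_control)]
  if (length(x) < 2 || length(y) < 2) {
    abort_circlin("each group needs at least 2 finite values")
  }
  norm_p <- c(case = NA_real_, control = NA_real_)
  if (test_policy == "auto") {
    if (length(x) >= 8 && length(y) >= 8 && sd(x) > 0 && sd(y) > 0) {
      norm_p["case"] <- dagostino_pearson_test(x)$p_value
      norm_p["control"] <- dagostino_pearson_test(y)$p_value
      test_used <- if (all(norm_p > normality_alpha)) "t" else "mann_whitney"
    } else {
      test_used <- "mann_whitney"
    }
  } else {
    test_used <- test_policy
  }
  fc <- mean(x) - mean(y)
  if (sd(c(x, y)) == 0) {                       # fully degenerate input
    p <- 1
  } else if (test_used == "t") {
    if (sd(x) == 0 && sd(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p <- stats::t.test(x, y, var.equal = var_equal)$p.value
    }
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE)$p.value)
    if (!is.finite(p)) p <- 1                   # all-tied ranks
  }
  list(p_value = min(1, max(p, 1e-300)), test_used = test_used,
       log2_fc_group = fc,
       normality_p_case = unname(norm_p["case"]),
       normality_p_control = unname(norm_p["control"]),
       n_case = length(x), n_control = length(y))
}

#' Differential analysis across features with two-stage FDR
#'
#' Runs [group_test()] per feature on a features x samples matrix of
#' log2-scale values (log2 circular fractions or log2 relative
#' expressions), then flags discoveries with the two-stage
#' Benjamini-Krieger-Yekutieli procedure at rate `q` across the feature
#' family. Missing cells are dropped per feature.
#'
#' @param feature_matrix numeric matrix, features x samples, with feature
#'   ids as row names and sample ids as column names.
#' @param metadata sample metadata (`sample_id`, `group`).
#' @param q FDR level (default 0.01).
#' @param test_policy forwarded to [group_test()].
#' @return tibble sorted by p-value: `feature_id`, `test_used`, `p_value`,
#'   `q_flag`, `log2_fc_group`, `normality_p_case`, `normality_p_control`,
#'   `n_case`, `n_control`.
#' @export
differential_analysis <- function(feature_matrix, metadata, q = 0.01,
                                  test_policy = "auto") {
  assert_two_groups(metadata)
  samples <- colnames(feature_matrix)
  grp <- metadata$group[match(samples, metadata$sample_id)]
  if (anyNA(grp)) abort_circlin("samples missing from metadata")
  rows <- lapply(rownames(feature_matrix), function(f) {
    v <- feature_matrix[f, ]
    res <- group_test(v[grp == "case"], v[grp == "control"],
                      test_policy = test_policy)
    tibble::tibble(feature_id = f, test_used = res$test_used,
                   p_value = res$p_value,
                   log2_fc_group = res$log2_fc_group,
                   normality_p_case = res$normality_p_case,
                   normality_p_control = res$normality_p_control,
                   n_case = res$n_case, n_control = res$n_control)
  })
  out <- dplyr::bind_rows(rows)
  fdr <- tsbky_fdr(out$p_value, q = q)
  out$q_flag <- fdr$reject
  out <- out[order(out$p_value), c("feature_id", "test_used", "p_value",
                                   "q_flag", "log2_fc_group",
                                   "normality_p_case", "normality_p_control",
                                   "n_case", "n_control")]
  out
}
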