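#' Per-sample circular-to-linear score
#'
#' For each feature, the per-sample log2 fold change is the log2-scale
#' value minus the control-group mean of that feature (a geometric-mean
#' reference on the linear scale); the score of a sample is the mean of
#' those fold changes over the significant feature set. By construction the
#' control-group mean score is 0 up to missing-data asymmetry. Samples with
#' no non-missing significant feature get no score.
#'
#' @param log2_matrix numeric matrix, features x samples, log2-scale
#'   (log2 circular fractions or log2 relative expression).
#' @param significant_features feature ids to average (non-empty subset of
#'   the row names).
#' @param metadata sample metadata (`sample_id`, `group`).
#' @return list of class `circlin_score`: `scores` tibble (`sample_id`,
#'   `score`, `n_features` used), `feature_set`, `control_means` (named
#'   per-feature control-group mean log2 values).
#' @export
circ_lin_score <- function(log2_matrix, significant_features, metadata) {
  assert_two_groups(metadata)
  if (length(significant_features) == 0) {
    abort_circlin("no significant features: no score definable")
  }
  missing_feat <- setdiff(significant_features, rownames(log2_matrix))
  if (length(missing_feat) > 0) {
    abort_circlin(paste0("significant feature(s) absent from matrix: ",
                         paste(missing_feat, collapse = ", ")))
  }
  samples <- colnames(log2_matrix)
  grp <- metadata$group[match(samples, metadata$sample_id)]
  sub <- log2_matrix[significant_features, , drop = FALSE]
  ctrl_means <- rowMeans(sub[, grp == "control", drop = FALSE], na.rm = TRUE)
  fc <- sweep(sub, 1, ctrl_means, `-`)
  n_feat <- colSums(!is.na(fc))
  score <- colMeans(fc, na.rm = TRUE)
  score[n_feat == 0] <- NA_real_
  structure(
    list(scores = tibble::tibble(sample_id = samples, score = unname(score),
                                 n_features = unname(n_feat)),
         feature_set = significant_features,
         control_means = ctrl_means),
    class = "circlin_score")
}

#' @export
print.circlin_score <- function(x, ...) {
  cat(sprintf("<circlin_score> %d samples, %d features averaged\n",
              nrow(x$scores), length(x$feature_set)))
  invisible(x)
}

#' ROC curve and AUC for a score against disease labels
#'
#' The AUC is the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) sample pairs in which the positive scores higher,
#' counting ties as half. Equal scores everywhere therefore give AUC 0.5.
#' The curve classifies a sample positive when its score reaches the
#' threshold; sensitivity is non-increasing as the threshold rises, and the
#' curve runs from (sensitivity, specificity) = (1, 0) at -Inf to (0, 1)
#' past the largest score. AUC is invariant under strictly monotone
#' transforms of the score.
#'
#' @param scores named numeric vector (names = sample ids) or the `scores`
#'   tibble of a [circ_lin_score()].
#' @param metadata sample metadata (`sample_id`, `group`).
#' @param positive_label the group treated as positive (default "case";
#'   higher score is expected to predict the positive class).
#' @return list of class `circlin_roc`: `curve` tibble (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`,
#'   `positive_label`.
#' @export
roc_auc <- function(scores, metadata, positive_label = "case") {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$sample_id)
  }
  scores <- scores[!is.na(scores)]
  grp <- metadata$group[match(names(scores), metadata$sample_id)]
  if (anyNA(grp)) abort_circlin("scored samples missing from metadata")
  pos <- scores[grp == positive_label]
  neg <- scores[grp != positive_label]
  if (length(pos) == 0 || length(neg) == 0) {
    abort_circlin("both classes must be present to compute a ROC curve")
  }
  r <- rank(c(pos, neg))                  # midranks handle ties (half credit)
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thresholds <- c(-Inf, sort(unique(scores)), Inf)
  curve <- tibble::tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thresholds, function(t) mean(neg < t), numeric(1)))
  structure(list(curve = curve, auc = auc, n_pos = length(pos),
                 n_neg = length(neg), positive_label = positive_label),
            class = "circlin_roc")
}

#' @export
print.circlin_roc <- function(x, ...) {
  cat(sprintf("<circlin_roc> AUC = %.3f (%d %s vs %d other)\n", x$auc,
              x$n_pos, x$positive_label, x$n_neg))
  invisible(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the conventional t-transform p-value
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df); |r| = 1 gives p = 0
#' by convention. Zero variance in either variable leaves the correlation
#' undefined and flags the result.
#'
#' @param x,y paired numeric vectors, n >= 3 complete pairs.
#' @return list: `r`, `p_value`, `n`, `defined`.
#' @export
pearson_with_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort_circlin("Pearson correlation needs >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    return(list(r = sign(r), p_value = 0, n = n, defined = TRUE))
  }
  p <- stats::cor.test(x, y, method = "pearson")$p.value
  list(r = r, p_value = p, n = n, defined = TRUE)
}

#' Compare scores between MIRS disease-stage strata
#'
#' Two-tailed two-sample Student t-test of case scores between the
#' lower-stage stratum (MIRS <= 3) and the higher-stage stratum
#' (MIRS >= 4). Controls and cases without a MIRS stage are excluded (the
#' latter with a message).
#'
#' @param scores named numeric vector or a [circ_lin_score()] `scores`
#'   tibble.
#' @param metadata sample metadata with `group` and `mirs_stage`.
#' @return list: `p_value`, `mean_low`, `mean_high`, `n_low`, `n_high`.
#' @export
mirs_group_compare <- function(scores, metadata) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$sample_id)
  }
  md <- metadata[metadata$group == "case", , drop = FALSE]
  md <- md[md$sample_id %in% names(scores), , drop = FALSE]
  no_stage <- is.na(md$mirs_stage)
  if (any(no_stage)) {
    message(sprintf("excluding %d case(s) without MIRS stage",
                    sum(no_stage)))
    md <- md[!no_stage, , drop = FALSE]
  }
  low <- scores[md$sample_id[md$mirs_stage <= 3]]
  high <- scores[md$sample_id[md$mirs_stage >= 4]]
  low <- low[!is.na(low)]; high <- high[!is.na(high)]
  if (length(low) < 2 || length(high) < 2) {
    abort_circlin("each MIRS stratum needs at least 2 scored cases")
  }
  if (sd(c(low, high)) == 0) {
    p <- 1
  } else {
    p <- stats::t.test(high, low, var.equal = TRUE)$p.value
  }
  list(p_value = p, mean_low = mean(low), mean_high = mean(high),
       n_low = length(low), n_high = length(high))
}

#' Percent exon exclusion from gel band intensities
#'
#' `100 * excl / (incl + excl)` per event and sample; invariant to scaling
#' both intensities. For inclusion-type assays the reported covariate is
#' still percent exclusion, so all events share one axis; the assay
#' direction is preserved as metadata. Records with both intensities zero
#' yield a missing percentage.
#'
#' @param splicing splicing tibble (`event_name`, `direction`, `sample_id`,
#'   `incl_intensity`, `excl_intensity`).
#' @return tibble: `event_name`, `direction`, `sample_id`, `percent`.
#' @export
exon_exclusion_percent <- function(splicing) {
  total <- splicing$incl_intensity + splicing$excl_intensity
  pct <- ifelse(total > 0, 100 * splicing$excl_intensity / total, NA_real_)
  tibble::tibble(event_name = splicing$event_name,
                 direction = splicing$direction,
                 sample_id = splicing$sample_id,
                 percent = pct)
}

#' Correlate features or scores with clinical/splicing covariates
#'
#' Pearson correlation ([pearson_with_p()]) of each feature row against
#' each covariate column, pairing by sample id and dropping incomplete
#' pairs per covariate. Cells with fewer than 3 complete pairs or an
#' undefined correlation are flagged.
#'
#' @param values named numeric vector (one feature), a features x samples
#'   matrix, or a tibble with `sample_id` and one column per feature.
#' @param covariates tibble with `sample_id` and one numeric column per
#'   covariate (e.g. MRC megascore, percent exon exclusion).
#' @return tibble: `feature`, `covariate`, `r`, `p_value`, `n`, `status`
#'   ("ok", "insufficient_n", "undefined").
#' @export
correlate_with_covariates <- function(values, covariates) {
  if (is.numeric(values) && !is.matrix(values)) {
    values <- matrix(values, nrow = 1,
                     dimnames = list("score", names(values)))
  } else if (is.data.frame(values)) {
    ids <- values$sample_id
    vm <- t(as.matrix(values[setdiff(names(values), "sample_id")]))
    colnames(vm) <- ids
    values <- vm
  }
  cov_names <- setdiff(names(covariates), "sample_id")
  rows <- list()
  for (f in rownames(values)) {
    v <- values[f, ]
    for (cv in cov_names) {
      cvv <- covariates[[cv]][match(colnames(values),
                                    covariates$sample_id)]
      keep <- is.finite(v) & is.finite(cvv)
      if (sum(keep) < 3) {
        res <- list(r = NA_real_, p_value = NA_real_, n = sum(keep),
                    defined = FALSE)
        status <- "insufficient_n"
      } else {
        res <- pearson_with_p(v[keep], cvv[keep])
        status <- if (res$defined) "ok" else "undefined"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature = f, covariate = cv, r = res$r, p_value = res$p_value,
        n = res$n, status = status)
    }
  }
  dplyr::bind_rows(rows)
}
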