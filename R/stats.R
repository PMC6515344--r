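# Distributional machinery for the differential-testing policy: the
# D'Agostino-Pearson omnibus normality test (not available in base R or the
# installed add-on packages, so implemented from the standard moment
# approximations) and the two-stage Benjamini-Krieger-Yekutieli adaptive
# FDR procedure.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness statistic (D'Agostino 1970) and the
#' transformed kurtosis statistic (Anscombe & Glynn 1983) into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires n >= 8 (the kurtosis approximation breaks
#' down below that).
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2), `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort_circlin("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) abort_circlin("zero variance: normality test undefined")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino's Z1
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe-Glynn Z2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n)
}

bh_stepup <- function(p, level) {
  m <- length(p)
  ord <- order(p)
  thresh <- seq_len(m) / m * level
  passed <- which(p[ord] <= thresh)
  reject <- logical(m)
  if (length(passed) > 0) reject[ord[seq_len(max(passed))]] <- TRUE
  reject
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' The adaptive two-stage linear step-up procedure: stage 1 applies
#' Benjamini-Hochberg at `q' = q / (1 + q)`; the number of stage-1
#' rejections r1 estimates the true-null count `m0 = m - r1`; if r1 = 0
#' nothing is rejected, if m0 = 0 everything is, otherwise stage 2 applies
#' Benjamini-Hochberg at `q' * m / m0`. Sandwiched between BH at
#' `q/(1+q)` and BH at `q' * m / m0` by construction.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q target false discovery rate (default 0.01).
#' @return list with `reject` (logical flags, input order), `n_rejected`,
#'   `stage1_rejections`, and `threshold` (the largest rejected p-value,
#'   NA when none).
#' @export
tsbky_fdr <- function(p_values, q = 0.01) {
  m <- length(p_values)
  if (m == 0) {
    return(list(reject = logical(0), n_rejected = 0L,
                stage1_rejections = 0L, threshold = NA_real_))
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort_circlin("p-values must lie in (0, 1]")
  }
  qprime <- q / (1 + q)
  stage1 <- bh_stepup(p_values, qprime)
  r1 <- sum(stage1)
  if (r1 == 0) {
    reject <- logical(m)
  } else if (r1 == m) {
    reject <- rep(TRUE, m)
  } else {
    m0 <- m - r1
    reject <- bh_stepup(p_values, qprime * m / m0)
  }
  list(reject = reject, n_rejected = sum(reject),
       stage1_rejections = as.integer(r1),
       threshold = if (any(reject)) max(p_values[reject]) else NA_real_)
}
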