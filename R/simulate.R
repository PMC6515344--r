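#' Simulation configuration for a synthetic case/control cohort
#'
#' Defines the generative model behind [simulate_cohort()]. Per gene g a
#' baseline expression `e_g ~ LogNormal(expr_meanlog, expr_sdlog)` (units:
#' junction reads per million) and a baseline circular share
#' `f_g ~ Beta(circ_fraction_alpha, circ_fraction_beta)` are drawn. Sample i
#' receives a library size `L_i ~ LogUniform(lib_size_range)`. Back-splice
#' reads are negative binomial with mean `L_i * e_g * f_gi * 1e-6` and
#' dispersion `alpha` (variance `mu + alpha * mu^2`); total linear-junction
#' reads are negative binomial with mean `L_i * e_g * (1 - f_gi) * 1e-6`,
#' split across 2-4 linear junctions sharing the back-splice donor or
#' acceptor site by per-gene Dirichlet weights. For planted (true-positive)
#' genes the circular-to-linear odds `f/(1-f)` of case samples are
#' multiplied by `ratio_fold^(1 - c + c * s_i)`, where `c` is
#' `severity_coupling` and `s_i ~ Uniform(0,1)` is the latent severity of
#' case i. Severity also drives the clinical covariates: MRC megascore
#' `mrc_baseline - mrc_drop * s_i + N(0, mrc_sigma)` (clipped at the control
#' baseline; controls sit exactly at baseline) and MIRS stage by severity
#' quartile mapped onto stages 2-5.
#'
#' @param n_cases,n_controls cohort sizes (defaults 30 and 29).
#' @param n_genes number of circRNA-hosting genes simulated.
#' @param n_true_positive number of genes with a planted ratio effect.
#' @param ratio_fold fold change applied to the circular-to-linear odds of
#'   cases at planted genes (theta; 1 = null).
#' @param dispersion negative-binomial dispersion alpha; 0 gives Poisson.
#' @param lib_size_range length-2 vector, reads per sample (default 5-20
#'   million, a desk-scale stand-in for deep ribo-depleted libraries).
#' @param circ_fraction_alpha,circ_fraction_beta Beta prior on the baseline
#'   circular share of expression.
#' @param fraction_bio_sd inter-individual biological variability of the
#'   circular fraction: per gene x sample log2-odds jitter SD, in log2
#'   units (default 0.65, i.e. roughly 1.6-fold person-to-person spread of
#'   the circular share, on top of qPCR technical noise); 0 disables it.
#' @param severity_coupling c in \[0,1\]: 0 = uniform effect in all cases,
#'   1 = effect fully proportional to latent severity.
#' @param mrc_baseline control-group MRC megascore (default 130).
#' @param mrc_drop maximum severity-driven MRC decrease.
#' @param mrc_sigma Gaussian noise (score points) on case MRC.
#' @param expr_meanlog,expr_sdlog log-normal parameters of gene expression
#'   (reads per million across both isoform classes).
#' @param ct_intercept qPCR calibration intercept: Ct = intercept -
#'   log2(abundance) (default 30 cycles at unit abundance).
#' @param ct_sigma technical Ct noise, cycles (default 0.25).
#' @param seed master integer seed; every emitted table is a deterministic
#'   function of it.
#' @return a validated list of class `circlin_config`.
#' @export
simulation_config <- function(n_cases = 30L, n_controls = 29L,
                              n_genes = 50L, n_true_positive = 5L,
                              ratio_fold = 2, dispersion = 0.1,
                              lib_size_range = c(5e6, 2e7),
                              circ_fraction_alpha = 2,
                              circ_fraction_beta = 8,
                              fraction_bio_sd = 0.65,
                              severity_coupling = 0.5,
                              mrc_baseline = 130, mrc_drop = 20,
                              mrc_sigma = 2,
                              expr_meanlog = log(50), expr_sdlog = 1,
                              ct_intercept = 30, ct_sigma = 0.25,
                              seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes),
              n_true_positive = as.integer(n_true_positive),
              ratio_fold = ratio_fold, dispersion = dispersion,
              lib_size_range = as.numeric(lib_size_range),
              circ_fraction_alpha = circ_fraction_alpha,
              circ_fraction_beta = circ_fraction_beta,
              fraction_bio_sd = fraction_bio_sd,
              severity_coupling = severity_coupling,
              mrc_baseline = mrc_baseline, mrc_drop = mrc_drop,
              mrc_sigma = mrc_sigma,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              ct_intercept = ct_intercept, ct_sigma = ct_sigma,
              seed = as.integer(seed))
  if (cfg$n_cases < 1 || cfg$n_controls < 1) {
    abort_circlin("n_cases and n_controls must be positive")
  }
  if (cfg$n_genes < 0) abort_circlin("n_genes must be non-negative")
  if (cfg$n_true_positive < 0 || cfg$n_true_positive > cfg$n_genes) {
    abort_circlin("n_true_positive must lie in [0, n_genes]")
  }
  if (!is.finite(cfg$ratio_fold) || cfg$ratio_fold <= 0) {
    abort_circlin("ratio_fold must be positive")
  }
  if (cfg$dispersion < 0) abort_circlin("dispersion must be >= 0")
  if (length(cfg$lib_size_range) != 2 || any(cfg$lib_size_range <= 0) ||
      cfg$lib_size_range[1] > cfg$lib_size_range[2]) {
    abort_circlin("lib_size_range must be an ordered pair of positive sizes")
  }
  if (cfg$circ_fraction_alpha <= 0 || cfg$circ_fraction_beta <= 0) {
    abort_circlin("Beta prior parameters must be positive")
  }
  if (cfg$fraction_bio_sd < 0) {
    abort_circlin("fraction_bio_sd must be >= 0")
  }
  if (cfg$severity_coupling < 0 || cfg$severity_coupling > 1) {
    abort_circlin("severity_coupling must lie in [0, 1]")
  }
  if (cfg$mrc_drop <= 0) abort_circlin("mrc_drop must be positive")
  if (cfg$ct_sigma < 0) abort_circlin("ct_sigma must be >= 0")
  structure(cfg, class = "circlin_config")
}

# multinomial split of totals (one per sample) over weights w, vectorized
# over samples via stick-breaking binomials: exact multinomial sampling.
split_multinomial <- function(totals, w) {
  k <- length(w)
  out <- matrix(0L, nrow = k, ncol = length(totals))
  remaining <- as.integer(totals)
  wrem <- 1
  for (j in seq_len(k - 1)) {
    pj <- if (wrem > 0) min(1, w[j] / wrem) else 0
    xj <- stats::rbinom(length(remaining), remaining, pj)
    out[j, ] <- xj
    remaining <- remaining - xj
    wrem <- wrem - w[j]
  }
  out[k, ] <- remaining
  out
}

rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

#' Simulate a synthetic case/control circRNA cohort
#'
#' Draws a full cohort under the generative model described in
#' [simulation_config()]: a back-splice [junction_count_table()], a long
#' linear-junction table, sample metadata with severity-driven clinical
#' covariates, and a ground-truth object for recovery tests. All randomness
#' is seeded from `config$seed` through per-table sub-streams, so a fixed
#' config reproduces every table exactly.
#'
#' @param config a [simulation_config()].
#' @return list with elements `backsplice` (junction_count_table, raw
#'   counts), `linear` (tibble: chrom, donor_pos, acceptor_pos, strand,
#'   sample_id, count), `metadata` (tibble: sample_id, group, mrc_megascore,
#'   mirs_stage), and `truth` (list: `true_positive_ids`, `severity` (named,
#'   cases only), `baseline_fraction`, `fraction` genes x samples matrix of
#'   realized circular shares, `expr`, `size_factor`, `lib_sizes`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "circlin_config"))
  ng <- config$n_genes
  sample_ids <- c(sprintf("case_%02d", seq_len(config$n_cases)),
                  sprintf("ctrl_%02d", seq_len(config$n_controls)))
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  ns <- length(sample_ids)

  set.seed(derive_seed(config$seed, "severity"))
  severity <- stats::runif(config$n_cases)
  names(severity) <- sample_ids[group == "case"]

  set.seed(derive_seed(config$seed, "clinical"))
  mrc_case <- config$mrc_baseline - config$mrc_drop * severity +
    stats::rnorm(config$n_cases, 0, config$mrc_sigma)
  mrc_case <- unname(pmin(mrc_case, config$mrc_baseline))
  mirs_case <- cut(unname(severity), breaks = c(0, 0.25, 0.5, 0.75, 1),
                   labels = FALSE, include.lowest = TRUE) + 1L
  metadata <- tibble::tibble(
    sample_id = sample_ids, group = group,
    mrc_megascore = c(mrc_case, rep(config$mrc_baseline, config$n_controls)),
    mirs_stage = c(mirs_case, rep(NA_integer_, config$n_controls)))

  set.seed(derive_seed(config$seed, "libsizes"))
  lr <- log(config$lib_size_range)
  lib_sizes <- round(exp(stats::runif(ns, lr[1], lr[2])))
  names(lib_sizes) <- sample_ids

  if (ng == 0) {
    events <- tibble::tibble(event_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             strand = character(), gene_id = character())
    counts <- matrix(numeric(), nrow = 0, ncol = ns,
                     dimnames = list(NULL, sample_ids))
    truth <- list(true_positive_ids = character(), severity = severity,
                  baseline_fraction = numeric(),
                  fraction = matrix(numeric(), 0, ns,
                                    dimnames = list(NULL, sample_ids)),
                  expr = numeric(), size_factor =
                    lib_sizes / mean(lib_sizes), lib_sizes = lib_sizes)
    linear <- tibble::tibble(chrom = character(), donor_pos = integer(),
                             acceptor_pos = integer(), strand = character(),
                             sample_id = character(), count = integer())
    return(list(backsplice = junction_count_table(events, counts, lib_sizes),
                linear = linear, metadata = metadata, truth = truth))
  }

  set.seed(derive_seed(config$seed, "genes"))
  gene_ids <- sprintf("GENE%03d", seq_len(ng))
  chrom <- sprintf("chr%d", (seq_len(ng) - 1L) %% 22L + 1L)
  start <- sample.int(1e8, ng) + 10000L
  end <- start + sample(500:20000, ng, replace = TRUE)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  e_g <- stats::rlnorm(ng, config$expr_meanlog, config$expr_sdlog)
  f_g <- stats::rbeta(ng, config$circ_fraction_alpha, config$circ_fraction_beta)
  names(e_g) <- names(f_g) <- gene_ids
  tp_ids <- gene_ids[seq_len(config$n_true_positive)]

  # realized circular share per gene x sample: planted odds multiplier in
  # cases at true-positive genes, scaled by latent severity
  odds <- matrix(f_g / (1 - f_g), nrow = ng, ncol = ns,
                 dimnames = list(gene_ids, sample_ids))
  if (length(tp_ids) > 0 && config$ratio_fold != 1) {
    cc <- config$severity_coupling
    mult <- config$ratio_fold^(1 - cc + cc * severity)
    odds[tp_ids, names(severity)] <-
      sweep(odds[tp_ids, names(severity), drop = FALSE], 2, mult, `*`)
  }
  if (config$fraction_bio_sd > 0) {
    set.seed(derive_seed(config$seed, "biovar"))
    odds <- odds * 2^matrix(stats::rnorm(ng * ns, 0, config$fraction_bio_sd),
                            nrow = ng)
  }
  fmat <- odds / (1 + odds)

  mu_scale <- outer(e_g, lib_sizes * 1e-6)        # genes x samples
  set.seed(derive_seed(config$seed, "counts"))
  circ_counts <- matrix(
    rnb(ng * ns, mu = as.vector(mu_scale * fmat), config$dispersion),
    nrow = ng, dimnames = list(gene_ids, sample_ids))
  lin_totals <- matrix(
    rnb(ng * ns, mu = as.vector(mu_scale * (1 - fmat)), config$dispersion),
    nrow = ng, dimnames = list(gene_ids, sample_ids))

  # per-gene linear junction geometry: 2-4 junctions, alternately sharing
  # the back-splice donor or acceptor site, with fixed Dirichlet weights
  set.seed(derive_seed(config$seed, "linear"))
  k_g <- sample(2:4, ng, replace = TRUE)
  donor <- ifelse(strand == "-", start, end)
  acceptor <- ifelse(strand == "-", end, start)
  lin_records <- vector("list", ng)
  for (g in seq_len(ng)) {
    k <- k_g[g]
    w <- stats::rgamma(k, 1); w <- w / sum(w)
    share_donor <- (seq_len(k) %% 2L) == 1L
    gap <- sample(200:5000, k, replace = TRUE)
    dirn <- if (strand[g] == "-") -1L else 1L
    dp <- ifelse(share_donor, donor[g], acceptor[g] - dirn * gap)
    ap <- ifelse(share_donor, donor[g] + dirn * gap, acceptor[g])
    split <- split_multinomial(lin_totals[g, ], w)
    lin_records[[g]] <- tibble::tibble(
      chrom = chrom[g],
      donor_pos = as.integer(rep(dp, ns)),
      acceptor_pos = as.integer(rep(ap, ns)),
      strand = strand[g],
      sample_id = rep(sample_ids, each = k),
      count = as.integer(split))
  }
  linear <- dplyr::bind_rows(lin_records)

  events <- tibble::tibble(
    event_id = make_event_id(chrom, start, end),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, gene_id = gene_ids)
  ord <- order(events$chrom, events$start, events$end, events$strand)
  events <- events[ord, ]
  circ_counts <- circ_counts[ord, , drop = FALSE]

  truth <- list(true_positive_ids = tp_ids, severity = severity,
                baseline_fraction = f_g, fraction = fmat, expr = e_g,
                size_factor = lib_sizes / mean(lib_sizes),
                lib_sizes = lib_sizes)
  list(backsplice = junction_count_table(events, circ_counts, lib_sizes),
       linear = linear, metadata = metadata, truth = truth)
}

#' Simulate a long-format qPCR Ct matrix from cohort ground truth
#'
#' Emits Ct values consistent with the cohort's abundances:
#' `Ct = ct_intercept - log2(size_factor_i * abundance) + N(0, ct_sigma)`,
#' where the circular isoform of gene g in sample i has abundance
#' `e_g * f_gi` and the linear isoform `e_g * (1 - f_gi)`. Reference genes
#' carry abundance equal to the per-sample size factor alone, so the
#' reference-averaged delta-Ct is an unbiased readout of -log2(abundance).
#'
#' @param config a [simulation_config()].
#' @param truth ground truth from [simulate_cohort()].
#' @param targets gene ids to assay (circular + linear isoforms each).
#' @param reference_genes reference assay names (default RPL13/RPL23/UBC).
#' @return tibble with columns `target_id`, `isoform`
#'   (circular/linear/reference), `sample_id`, `replicate`, `ct`.
#' @export
simulate_ct_matrix <- function(config, truth, targets,
                               reference_genes = c("RPL13", "RPL23", "UBC")) {
  stopifnot(inherits(config, "circlin_config"))
  empty <- tibble::tibble(target_id = character(), isoform = character(),
                          sample_id = character(), replicate = integer(),
                          ct = numeric())
  if (length(targets) == 0) return(empty)
  unknown <- setdiff(targets, rownames(truth$fraction))
  if (length(unknown) > 0) {
    abort_circlin(paste0("unknown target id(s): ",
                         paste(unknown, collapse = ", ")))
  }
  set.seed(derive_seed(config$seed, "ct"))
  sample_ids <- colnames(truth$fraction)
  sf <- truth$size_factor[sample_ids]
  rows <- list()
  for (tg in targets) {
    f <- truth$fraction[tg, sample_ids]
    e <- truth$expr[tg]
    for (iso in c("circular", "linear")) {
      ab <- if (iso == "circular") e * f else e * (1 - f)
      ct <- config$ct_intercept - log2(sf * ab) +
        stats::rnorm(length(sample_ids), 0, config$ct_sigma)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target_id = tg, isoform = iso, sample_id = sample_ids,
        replicate = 1L, ct = unname(ct))
    }
  }
  for (rg in reference_genes) {
    ct <- config$ct_intercept - log2(sf) +
      stats::rnorm(length(sample_ids), 0, config$ct_sigma)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      target_id = rg, isoform = "reference", sample_id = sample_ids,
      replicate = 1L, ct = unname(ct))
  }
  dplyr::bind_rows(rows)
}

#' Default alternative-splicing event descriptors
#'
#' Three cassette-exon events of the kind tracked as DM1 spliceopathy
#' biomarkers: two exclusion-type assays and one inclusion-type assay. The
#' reported covariate is percent exon exclusion for all three, rising with
#' disease severity.
#'
#' @param noise_sd Gaussian noise on the percentage, points (default 2).
#' @return tibble of event descriptors for [simulate_splicing_table()].
#' @export
default_splicing_events <- function(noise_sd = 2) {
  tibble::tibble(
    event_name = c("INSR_e11", "CAPZB_e8", "NFIX_e11"),
    direction = c("exclusion", "exclusion", "inclusion"),
    baseline = c(10, 15, 20),
    slope = c(50, 45, 40),
    noise_sd = noise_sd)
}

#' Simulate an RT-PCR splicing table coupled to latent severity
#'
#' Percent exon exclusion for case i is `baseline + slope * s_i + noise`
#' (controls: `baseline + noise`), clipped to \[0, 100\]. The implied
#' inclusion/exclusion band-intensity pair is emitted at an arbitrary total
#' intensity so gel quantification can be round-trip tested against
#' [exon_exclusion_percent()].
#'
#' @param config a [simulation_config()].
#' @param truth ground truth from [simulate_cohort()].
#' @param events descriptor tibble: `event_name`, `direction`
#'   (exclusion/inclusion), `baseline` (percent, in \[0,100\]), `slope`
#'   (percent per unit severity), `noise_sd` (percent).
#' @return tibble: `event_name`, `direction`, `sample_id`,
#'   `incl_intensity`, `excl_intensity`, `percent`.
#' @export
simulate_splicing_table <- function(config, truth,
                                    events = default_splicing_events()) {
  stopifnot(inherits(config, "circlin_config"))
  events <- tibble::as_tibble(events)
  if (any(events$baseline < 0 | events$baseline > 100)) {
    abort_circlin("splicing baseline percentages must lie in [0, 100]")
  }
  if (!all(events$direction %in% c("exclusion", "inclusion"))) {
    abort_circlin("splicing direction must be 'exclusion' or 'inclusion'")
  }
  set.seed(derive_seed(config$seed, "splicing"))
  sample_ids <- names(truth$lib_sizes)
  sev <- rep(0, length(sample_ids))
  names(sev) <- sample_ids
  sev[names(truth$severity)] <- truth$severity
  is_case <- sample_ids %in% names(truth$severity)
  rows <- list()
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    p <- ev$baseline + ifelse(is_case, ev$slope * sev, 0) +
      stats::rnorm(length(sample_ids), 0, ev$noise_sd)
    p <- unname(pmin(100, pmax(0, p)))
    total <- stats::runif(length(sample_ids), 500, 2000)
    rows[[r]] <- tibble::tibble(
      event_name = ev$event_name, direction = ev$direction,
      sample_id = sample_ids,
      incl_intensity = total * (1 - p / 100),
      excl_intensity = total * p / 100,
      percent = p)
  }
  dplyr::bind_rows(rows)
}
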