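test_that("config validation rejects impossible cohorts", {
  expect_error(simulation_config(n_cases = 0), "positive")
  expect_error(simulation_config(n_true_positive = 10, n_genes = 5),
               "n_true_positive")
  expect_error(simulation_config(ratio_fold = 0), "ratio_fold")
  expect_error(simulation_config(lib_size_range = c(2e7, 5e6)), "ordered")
  expect_error(simulation_config(severity_coupling = 1.5), "severity")
})

test_that("a fixed seed reproduces every table exactly", {
  cfg <- simulation_config(n_genes = 12, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$backsplice$counts, b$backsplice$counts)
  expect_identical(a$linear, b$linear)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$fraction, b$truth$fraction)
  ct_a <- simulate_ct_matrix(cfg, a$truth, names(a$truth$expr)[1:3])
  ct_b <- simulate_ct_matrix(cfg, b$truth, names(b$truth$expr)[1:3])
  expect_identical(ct_a, ct_b)
})

test_that("cohort structure matches the configured design", {
  cfg <- simulation_config(n_cases = 7, n_controls = 5, n_genes = 9,
                           n_true_positive = 3, seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$backsplice$counts), c(9, 12))
  expect_equal(sum(co$metadata$group == "case"), 7)
  expect_length(co$truth$severity, 7)
  expect_setequal(names(co$truth$severity),
                  co$metadata$sample_id[co$metadata$group == "case"])
  expect_length(co$truth$true_positive_ids, 3)
  expect_true(all(co$truth$baseline_fraction > 0 &
                    co$truth$baseline_fraction < 1))
  # linear junctions share a coordinate with their event's donor or acceptor
  ev <- co$backsplice$events
  lj <- unique(co$linear[c("chrom", "donor_pos", "acceptor_pos", "strand")])
  anchors <- c(ev$start, ev$end)
  expect_true(all(lj$donor_pos %in% anchors | lj$acceptor_pos %in% anchors))
  # controls sit exactly at the MRC baseline; cases never exceed it
  ctrl <- co$metadata[co$metadata$group == "control", ]
  expect_true(all(ctrl$mrc_megascore == cfg$mrc_baseline))
  expect_true(all(co$metadata$mrc_megascore <= cfg$mrc_baseline))
  expect_true(all(co$metadata$mirs_stage[co$metadata$group == "case"] %in% 2:5))
})

test_that("an empty gene set yields empty tables but valid metadata", {
  cfg <- simulation_config(n_genes = 0, n_true_positive = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$backsplice$events), 0)
  expect_equal(nrow(co$linear), 0)
  expect_equal(nrow(co$metadata), 59)
  expect_length(co$truth$true_positive_ids, 0)
  expect_identical(simulate_ct_matrix(cfg, co$truth, character()),
                   simulate_ct_matrix(cfg, co$truth, character()))
  expect_equal(nrow(simulate_ct_matrix(cfg, co$truth, character())), 0)
})

test_that("severity decreasing implies MRC non-increasing when noiseless", {
  cfg <- simulation_config(n_genes = 2, n_true_positive = 0, mrc_sigma = 0, seed = 11)
  co <- simulate_cohort(cfg)
  cases <- co$metadata[co$metadata$group == "case", ]
  s <- co$truth$severity[cases$sample_id]
  ord <- order(s, decreasing = TRUE)
  expect_true(all(diff(cases$mrc_megascore[ord]) >= 0))
})

test_that("expected circular plus linear reads conserve gene expression", {
  # with zero dispersion and no fraction jitter, group means approach the
  # deterministic budget L_i * e_g * 1e-6 per gene
  cfg <- simulation_config(n_cases = 150, n_controls = 150, n_genes = 6,
                           n_true_positive = 0, dispersion = 0,
                           fraction_bio_sd = 0,
                           lib_size_range = c(1e7, 1e7), seed = 8)
  co <- simulate_cohort(cfg)
  lin_tot <- co$linear |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = sum(count))
  gene_budget <- sum(co$truth$expr) * 1e7 * 1e-6
  total <- mean(colSums(co$backsplice$counts) +
                  lin_tot$n[match(colnames(co$backsplice$counts),
                                  lin_tot$sample_id)])
  expect_lt(abs(total / gene_budget - 1), 0.02)
})

test_that("a planted odds fold change reproduces as a ratio fold change", {
  # theta = 2 with uniform coupling: the case/control ratio of mean
  # circular-to-linear ratios should recover the planted fold
  folds <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_cases = 200, n_controls = 200, n_genes = 8,
                             n_true_positive = 4, ratio_fold = 2,
                             severity_coupling = 0, dispersion = 0.01,
                             seed = s)
    co <- simulate_cohort(cfg)
    rm <- ratio_matrix(normalize_per_million(co$backsplice), {
      lin <- co$linear
      lin$count <- lin$count * 1e6 / co$truth$lib_sizes[lin$sample_id]
      lin
    }, co$metadata)
    tp_events <- co$backsplice$events$event_id[
      co$backsplice$events$gene_id %in% co$truth$true_positive_ids]
    s <- rm$summary[rm$summary$event_id %in% tp_events, ]
    mean(s$mean_ratio_case / s$mean_ratio_control)
  })
  expect_gt(mean(folds), 1.8)
  expect_lt(mean(folds), 2.2)
})

test_that("theta = 1 leaves group ratio distributions equal in law", {
  diffs <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_genes = 10, n_true_positive = 5,
                             ratio_fold = 1, seed = s)
    co <- simulate_cohort(cfg)
    m <- cohort_fraction_matrix(cfg, co, names(co$truth$expr))
    grp <- co$metadata$group[match(colnames(m), co$metadata$sample_id)]
    mean(rowMeans(m[, grp == "case"]) - rowMeans(m[, grp == "control"]))
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("Ct values encode isoform abundances exactly when noiseless", {
  cfg <- simulation_config(n_genes = 4, n_true_positive = 0, ct_sigma = 0,
                           seed = 21)
  co <- simulate_cohort(cfg)
  g <- names(co$truth$expr)[1]
  ct <- simulate_ct_matrix(cfg, co$truth, g)
  fr <- circ_fraction(ct, g)
  # dct = Ct_circ - Ct_lin = -log2(odds): recover the simulated fraction
  odds <- co$truth$fraction[g, fr$sample_id] /
    (1 - co$truth$fraction[g, fr$sample_id])
  expect_equal(fr$dct, unname(-log2(odds)), tolerance = 1e-12)
  # forced half abundance: odds 1/2 means one full cycle later
  truth2 <- co$truth
  truth2$fraction[g, ] <- 1 / 3
  ct2 <- simulate_ct_matrix(cfg, truth2, g)
  fr2 <- circ_fraction(ct2, g)
  expect_equal(fr2$dct, rep(1, nrow(fr2)), tolerance = 1e-12)
})

test_that("planted theta = 4 shifts the group Ct difference by 2 cycles", {
  cfg <- simulation_config(n_genes = 6, n_true_positive = 2, ratio_fold = 4,
                           severity_coupling = 0, fraction_bio_sd = 0,
                           ct_sigma = 0, seed = 17)
  co <- simulate_cohort(cfg)
  tp <- co$truth$true_positive_ids[1]
  fr <- circ_fraction(simulate_ct_matrix(cfg, co$truth, tp), tp)
  grp <- co$metadata$group[match(fr$sample_id, co$metadata$sample_id)]
  # Ct_lin - Ct_circ = -dct rises by log2(4) = 2 in cases
  expect_equal(mean(-fr$dct[grp == "case"]) - mean(-fr$dct[grp == "control"]),
               2, tolerance = 1e-9)
  shift <- mean(sapply(1:15, function(s) {
    cfgs <- simulation_config(n_genes = 6, n_true_positive = 2,
                              ratio_fold = 4, severity_coupling = 0,
                              fraction_bio_sd = 0, ct_sigma = 0.3, seed = s)
    cos <- simulate_cohort(cfgs)
    tps <- cos$truth$true_positive_ids[1]
    frs <- circ_fraction(simulate_ct_matrix(cfgs, cos$truth, tps), tps)
    g <- cos$metadata$group[match(frs$sample_id, cos$metadata$sample_id)]
    mean(-frs$dct[g == "case"]) - mean(-frs$dct[g == "control"])
  }))
  expect_equal(shift, 2, tolerance = 0.15)
})

test_that("unknown Ct targets are rejected", {
  cfg <- simulation_config(n_genes = 3, n_true_positive = 0, seed = 2)
  co <- simulate_cohort(cfg)
  expect_error(simulate_ct_matrix(cfg, co$truth, "NOPE"), "unknown target")
})

test_that("splicing percentages track the generative model", {
  cfg <- simulation_config(n_genes = 0, n_true_positive = 0, seed = 5)
  co <- simulate_cohort(cfg)
  flat <- tibble::tibble(event_name = "EV", direction = "exclusion",
                         baseline = 40, slope = 0, noise_sd = 0)
  sp <- simulate_splicing_table(cfg, co$truth, flat)
  expect_true(all(sp$percent == 40))
  # band pair round trip through gel quantification
  expect_equal(exon_exclusion_percent(sp)$percent, sp$percent,
               tolerance = 1e-9)
  expect_error(simulate_splicing_table(
    cfg, co$truth, tibble::tibble(event_name = "x", direction = "exclusion",
                                  baseline = 120, slope = 0, noise_sd = 0)),
    "baseline")
})

test_that("steep severity slopes give near-perfect severity correlation", {
  ok <- sapply(1:100, function(s) {
    cfg <- simulation_config(n_genes = 0, n_true_positive = 0, seed = s)
    co <- simulate_cohort(cfg)
    ev <- tibble::tibble(event_name = "EV", direction = "exclusion",
                         baseline = 30, slope = 30, noise_sd = 2)
    sp <- simulate_splicing_table(cfg, co$truth, ev)
    cases <- names(co$truth$severity)
    p <- sp$percent[match(cases, sp$sample_id)]
    cor(p, co$truth$severity) > 0.9
  })
  expect_gte(mean(ok), 0.95)
})
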