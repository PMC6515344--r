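simple_table <- function(counts, strand = "+") {
  ne <- nrow(counts)
  events <- tibble::tibble(
    event_id = sprintf("chr1:%d|%d", 100 * seq_len(ne),
                       100 * seq_len(ne) + 50),
    chrom = "chr1", start = 100L * seq_len(ne),
    end = 100L * seq_len(ne) + 50L, strand = strand,
    gene_id = sprintf("G%d", seq_len(ne)))
  junction_count_table(events, counts,
                       setNames(rep(1e6, ncol(counts)), colnames(counts)))
}

test_that("per-million normalization scales by library size", {
  counts <- matrix(c(10, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  ev <- tibble::tibble(event_id = "chr1:1|5", chrom = "chr1", start = 1L,
                       end = 5L, strand = "+", gene_id = "G")
  tab <- junction_count_table(ev, counts, c(a = 1e6, b = 2e6))
  norm <- normalize_per_million(tab)
  expect_equal(unname(norm$counts[1, ]), c(10, 0))
  expect_true(norm$normalized)
  expect_error(normalize_per_million(norm), "already")
  # doubling counts and library sizes leaves the output unchanged
  tab2 <- junction_count_table(ev, counts * 2, c(a = 2e6, b = 4e6))
  expect_equal(normalize_per_million(tab2)$counts, norm$counts)
})

test_that("presence filter applies the 70% either/both group rule", {
  md <- make_metadata(4, 4)
  counts <- matrix(0, 3, 8, dimnames = list(NULL, md$sample_id))
  counts[1, ] <- c(1, 0, 0, 0, 1, 1, 1, 0)  # 1/4 cases, 3/4 controls
  counts[2, ] <- 1                           # everywhere
  counts[3, ] <- c(1, 1, 1, 1, 0, 0, 0, 0)  # cases only
  tab <- simple_table(counts)
  either <- presence_filter(tab, md, min_fraction = 0.7, mode = "either")
  expect_setequal(either$events$gene_id, c("G1", "G2", "G3"))
  both <- presence_filter(tab, md, min_fraction = 0.7, mode = "both")
  expect_setequal(both$events$gene_id, "G2")
  # min_fraction 0 is the identity
  expect_identical(presence_filter(tab, md, min_fraction = 0)$events,
                   tab$events)
  md_onegroup <- md; md_onegroup$group <- "case"
  expect_error(presence_filter(tab, md_onegroup), "zero samples")
})

test_that("raising min_fraction never adds events (monotonicity)", {
  set.seed(4)
  md <- make_metadata(6, 5)
  counts <- matrix(rbinom(20 * 11, 1, 0.6) * rpois(20 * 11, 4), 20, 11,
                   dimnames = list(NULL, md$sample_id))
  tab <- simple_table(counts)
  kept <- sapply(seq(0, 1, by = 0.1), function(f)
    nrow(presence_filter(tab, md, min_fraction = f)$events))
  expect_true(all(diff(kept) <= 0))
})

test_that("the ratio uses the most abundant donor- or acceptor-sharing junction", {
  ev <- list(chrom = "chr1", start = 100L, end = 500L, strand = "+")
  lin <- tibble::tibble(
    chrom = "chr1",
    donor_pos = c(500L, 500L, 900L),
    acceptor_pos = c(800L, 900L, 100L),
    strand = "+", sample_id = "s1",
    count = c(20, 5, 8))
  r <- circ_lin_ratio(ev, 10, lin, "s1")
  expect_equal(r$ratio, 0.5)              # 10 / max(20, 5, 8)
  expect_equal(r$status, "ok")
  expect_equal(unname(r$partner["donor_pos"]), 500L)

  none <- circ_lin_ratio(ev, 12, lin[0, ], "s1")
  expect_equal(none$status, "no_linear_partner")
  expect_true(is.na(none$ratio))

  zc <- circ_lin_ratio(ev, 0, lin, "s1")
  expect_equal(zc$ratio, 0)
  expect_equal(zc$status, "zero_circ")

  bz <- circ_lin_ratio(ev, 0, lin[0, ], "s1")
  expect_equal(bz$status, "both_zero")

  # strand-incompatible junctions are not candidates
  lin_minus <- lin; lin_minus$strand <- "-"
  expect_equal(circ_lin_ratio(ev, 10, lin_minus, "s1")$status,
               "no_linear_partner")
  # "." strand matches either orientation
  lin_dot <- lin; lin_dot$strand <- "."
  expect_equal(circ_lin_ratio(ev, 10, lin_dot, "s1")$ratio, 0.5)
})

test_that("ratio > 0.5 screening flags the hand-counted events", {
  # 7 events, one sample; hand computation marks events 1, 4, 6 as > 0.5
  bs <- c(30, 5, 0, 80, 10, 12, 7)
  lmax <- c(40, 20, 15, 100, 50, 10, 14)
  events <- tibble::tibble(
    event_id = sprintf("chr1:%d|%d", 1000L * 1:7, 1000L * 1:7 + 200L),
    chrom = "chr1", start = 1000L * 1:7, end = 1000L * 1:7 + 200L,
    strand = "+", gene_id = sprintf("G%d", 1:7))
  lin <- tibble::tibble(chrom = "chr1", donor_pos = events$end,
                        acceptor_pos = events$end + 500L, strand = "+",
                        sample_id = "s1", count = lmax)
  md <- tibble::tibble(sample_id = c("s1", "s2"),
                       group = c("case", "control"))
  lin2 <- dplyr::bind_rows(lin, dplyr::mutate(lin, sample_id = "s2"))
  counts2 <- cbind(matrix(bs, 7, 1, dimnames = list(NULL, "s1")),
                   matrix(0, 7, 1, dimnames = list(NULL, "s2")))
  tab2 <- junction_count_table(events, counts2, c(s1 = 1e6, s2 = 1e6))
  rm <- ratio_matrix(tab2, lin2, md)
  flagged <- which(rm$ratio[, "s1"] > 0.5)
  expect_equal(unname(flagged), c(1, 4, 6))
  expect_equal(unname(rm$ratio[, "s1"]), bs / lmax)
})

test_that("ratio_matrix equals the brute-force per-cell oracle", {
  for (s in 1:20) {
    fx <- random_ratio_fixture(s)
    md <- tibble::tibble(sample_id = fx$samples,
                         group = rep(c("case", "control"),
                                     length.out = length(fx$samples)))
    rm <- ratio_matrix(fx$table, fx$linear, md)
    for (i in seq_len(nrow(fx$table$events))) {
      for (sm in fx$samples) {
        want <- oracle_ratio_cell(fx$table$events[i, ],
                                  fx$table$counts[i, sm], fx$linear, sm)
        expect_identical(rm$status[i, sm], want$status)
        if (want$status %in% c("ok", "zero_circ")) {
          expect_equal(rm$ratio[i, sm], want$ratio)
        } else {
          expect_true(is.na(rm$ratio[i, sm]))
        }
      }
    }
  }
})

test_that("ratios are invariant to library-size normalization", {
  cfg <- simulation_config(n_genes = 10, seed = 31)
  co <- simulate_cohort(cfg)
  rm_raw <- ratio_matrix(co$backsplice, co$linear, co$metadata)
  norm <- normalize_per_million(co$backsplice)
  lin_norm <- co$linear
  lin_norm$count <- lin_norm$count * 1e6 / co$truth$lib_sizes[lin_norm$sample_id]
  rm_norm <- ratio_matrix(norm, lin_norm, co$metadata)
  expect_equal(rm_raw$ratio, rm_norm$ratio, tolerance = 1e-12)
  expect_identical(rm_raw$status, rm_norm$status)
})

test_that("ratio_matrix handles degenerate linear tables", {
  md <- make_metadata(1, 1)
  counts <- matrix(c(3, 0, 0, 2), 2, 2,
                   dimnames = list(NULL, md$sample_id))
  tab <- simple_table(counts)
  empty_lin <- tibble::tibble(chrom = character(), donor_pos = integer(),
                              acceptor_pos = integer(), strand = character(),
                              sample_id = character(), count = integer())
  rm <- ratio_matrix(tab, empty_lin, md)
  expect_true(all(rm$status %in% c("no_linear_partner", "both_zero")))
  expect_true(all(is.na(rm$ratio)))
})

test_that("candidate intersection matches event- and gene-level keys", {
  events <- tibble::tibble(
    event_id = c("chr1:1|5", "chr1:10|50", "chr2:3|9"),
    chrom = c("chr1", "chr1", "chr2"), start = c(1L, 10L, 3L),
    end = c(5L, 50L, 9L), strand = "+",
    gene_id = c("GENE_A", "GENE_A", "GENE_B"))
  hit <- intersect_candidates(events, "GENE_A")
  expect_equal(nrow(hit), 2)              # gene key returns all isoforms
  expect_true(all(hit$match_key == "gene_id"))
  by_event <- intersect_candidates(events, "chr2:3|9")
  expect_equal(by_event$gene_id, "GENE_B")
  expect_equal(nrow(intersect_candidates(events, character())), 0)
  ghost <- intersect_candidates(events, c("GENE_A", "GENE_ZZ"))
  expect_equal(attr(ghost, "unmatched"), "GENE_ZZ")
})
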