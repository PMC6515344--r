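# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: plain loops and enumeration.

# naive per-cell circular-to-linear ratio: scan every linear junction
oracle_ratio_cell <- function(ev, bs_count, linear, sample) {
  if (ev$strand == "+") {
    donors <- ev$end; acceptors <- ev$start
  } else if (ev$strand == "-") {
    donors <- ev$start; acceptors <- ev$end
  } else {
    donors <- c(ev$start, ev$end); acceptors <- c(ev$start, ev$end)
  }
  lstar <- 0
  for (i in seq_len(nrow(linear))) {
    lj <- linear[i, ]
    if (lj$sample_id != sample || lj$chrom != ev$chrom) next
    if (!(lj$strand == ev$strand || lj$strand == "." || ev$strand == ".")) next
    if (lj$donor_pos %in% donors || lj$acceptor_pos %in% acceptors) {
      lstar <- max(lstar, lj$count)
    }
  }
  if (lstar > 0 && bs_count > 0) list(ratio = bs_count / lstar, status = "ok")
  else if (lstar > 0) list(ratio = 0, status = "zero_circ")
  else if (bs_count > 0) list(ratio = NA_real_, status = "no_linear_partner")
  else list(ratio = NA_real_, status = "both_zero")
}

# brute-force AUC by pair counting with half credit for ties
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  r <- rank(pooled)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# random junction-count fixture: <= 20 events, <= 10 samples, with linear
# junctions that sometimes share the back-splice donor/acceptor sites
random_ratio_fixture <- function(seed) {
  set.seed(seed)
  ne <- sample(1:20, 1); ns <- sample(2:10, 1)
  samples <- sprintf("s%02d", seq_len(ns))
  chrom <- sample(c("chr1", "chr2"), ne, replace = TRUE)
  start <- sample(1000:5000, ne)
  end <- start + sample(100:1000, ne, replace = TRUE)
  strand <- sample(c("+", "-", "."), ne, replace = TRUE, prob = c(.45, .45, .1))
  events <- tibble::tibble(
    event_id = sprintf("%s:%d|%d", chrom, start, end),
    chrom = chrom, start = start, end = end, strand = strand,
    gene_id = sprintf("G%02d", seq_len(ne)))
  counts <- matrix(rpois(ne * ns, 5), ne, ns,
                   dimnames = list(events$event_id, samples))
  nl <- sample(5:60, 1)
  anchor <- sample(seq_len(ne), nl, replace = TRUE)
  use_donor <- runif(nl) < 0.5
  dp <- ifelse(use_donor,
               ifelse(strand[anchor] == "-", start[anchor], end[anchor]),
               sample(6000:9000, nl, replace = TRUE))
  ap <- ifelse(use_donor, sample(6000:9000, nl, replace = TRUE),
               ifelse(strand[anchor] == "-", end[anchor], start[anchor]))
  linear <- tibble::tibble(
    chrom = chrom[anchor], donor_pos = as.integer(dp),
    acceptor_pos = as.integer(ap),
    strand = sample(c("+", "-", "."), nl, replace = TRUE,
                    prob = c(.4, .4, .2)),
    sample_id = sample(samples, nl, replace = TRUE),
    count = rpois(nl, 8))
  linear <- linear[linear$donor_pos != linear$acceptor_pos, ]
  lib <- setNames(rep(1e6, ns), samples)
  list(table = junction_count_table(events, counts, lib),
       linear = linear, samples = samples)
}

make_metadata <- function(n_case, n_control) {
  tibble::tibble(
    sample_id = c(sprintf("case_%02d", seq_len(n_case)),
                  sprintf("ctrl_%02d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    mrc_megascore = NA_real_, mirs_stage = NA_integer_)
}

# qPCR-arm helper: log2 circular fraction matrix straight from a cohort
cohort_fraction_matrix <- function(cfg, cohort, targets) {
  ct <- simulate_ct_matrix(cfg, cohort$truth, targets)
  fr <- circ_fraction(ct, targets)
  wide <- tidyr::pivot_wider(fr[c("target_id", "sample_id", "log2_fraction")],
                             names_from = "sample_id",
                             values_from = "log2_fraction")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$target_id
  m
}

ct_fixture <- function() {
  # refs average 21 in every sample; case_01 target Ct 23 (dCt 2),
  # controls both dCt 3 -> case ddCt = -1 -> rel_expr 2
  samples <- c("case_01", "ctrl_01", "ctrl_02")
  refs <- tidyr::expand_grid(
    target_id = c("RPL13", "RPL23", "UBC"), sample_id = samples)
  refs$isoform <- "reference"
  refs$replicate <- 1L
  refs$ct <- rep(c(20, 21, 22), each = 3)
  tg <- tibble::tibble(target_id = "G1", isoform = "circular",
                       sample_id = samples, replicate = 1L,
                       ct = c(23, 24, 24))
  dplyr::bind_rows(refs, tg)
}

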