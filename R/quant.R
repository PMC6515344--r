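#' Normalize junction counts to counts per million
#'
#' `count' = count * 1e6 / lib_size(sample)`. Ratios downstream are
#' invariant to this scaling (both isoform classes share the sample's
#' library size), but normalized counts make abundances comparable across
#' libraries of different depth.
#'
#' @param table a raw-count [junction_count_table()].
#' @return the table with per-million counts and `normalized = TRUE`.
#' @export
normalize_per_million <- function(table) {
  stopifnot(inherits(table, "junction_count_table"))
  if (table$normalized) abort_circlin("table is already normalized")
  if (is.null(table$lib_sizes)) abort_circlin("lib_sizes required")
  ls <- table$lib_sizes[colnames(table$counts)]
  if (any(ls == 0)) abort_circlin("zero library size")
  counts <- sweep(table$counts, 2, ls / 1e6, `/`)
  junction_count_table(table$events, counts, lib_sizes = table$lib_sizes,
                       normalized = TRUE)
}

#' Group-wise presence filter for back-splice events
#'
#' An event is "present" in a sample when its count exceeds zero (a
#' detection criterion, deliberately not an abundance threshold). With
#' `mode = "either"` (default) an event is kept when its presence fraction
#' reaches `min_fraction` in the control group OR in the case group;
#' `mode = "both"` requires both groups. Event order is preserved.
#'
#' @param table a [junction_count_table()].
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param min_fraction minimum presence fraction (default 0.7).
#' @param mode `"either"` or `"both"`.
#' @return the filtered [junction_count_table()].
#' @export
presence_filter <- function(table, metadata, min_fraction = 0.7,
                            mode = c("either", "both")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "junction_count_table"))
  assert_two_groups(metadata)
  samples <- colnames(table$counts)
  grp <- metadata$group[match(samples, metadata$sample_id)]
  if (anyNA(grp)) abort_circlin("samples missing from metadata")
  for (g in c("case", "control")) {
    if (sum(grp == g) == 0) {
      abort_circlin(sprintf("group '%s' has zero samples", g))
    }
  }
  if (nrow(table$events) == 0) return(table)
  present <- table$counts > 0
  frac_case <- rowMeans(present[, grp == "case", drop = FALSE])
  frac_ctrl <- rowMeans(present[, grp == "control", drop = FALSE])
  keep <- if (mode == "either") {
    frac_case >= min_fraction | frac_ctrl >= min_fraction
  } else {
    frac_case >= min_fraction & frac_ctrl >= min_fraction
  }
  junction_count_table(table$events[keep, , drop = FALSE],
                       table$counts[keep, , drop = FALSE],
                       lib_sizes = table$lib_sizes,
                       normalized = table$normalized)
}

strand_compatible <- function(a, b) a == b | a == "." | b == "."

#' Circular-to-linear ratio for one event in one sample
#'
#' Candidate linear junctions are those on the same chromosome (strand
#' equal, unless either strand is ".") whose donor position equals the
#' event's donor coordinate OR whose acceptor position equals the event's
#' acceptor coordinate (donor = event end on the + strand, event start on
#' the - strand; "." events match in either orientation). The ratio divides
#' the back-splice count by the highest candidate count, so both numerator
#' and denominator are reads spanning a single splice junction. Division by
#' zero is never emitted: a back-splice with no expressed linear partner is
#' reported as status `no_linear_partner` ("circular only").
#'
#' @param event one-row tibble (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param bs_count back-splice count for the sample (same normalization
#'   scale as `linear`).
#' @param linear linear junction tibble (`chrom`, `donor_pos`,
#'   `acceptor_pos`, `strand`, `sample_id`, `count`).
#' @param sample_id which sample to evaluate.
#' @return list with `ratio` (NA when undefined), `status` (one of `ok`,
#'   `zero_circ`, `no_linear_partner`, `both_zero`), `linear_count`, and
#'   `partner` (donor/acceptor of the chosen junction, NA when none; ties
#'   broken by smallest donor then acceptor position).
#' @export
circ_lin_ratio <- function(event, bs_count, linear, sample_id) {
  keys <- event_match_keys(event$chrom, event$start, event$end, event$strand)
  cand <- linear[linear$sample_id == sample_id &
                   linear$chrom == event$chrom &
                   strand_compatible(linear$strand, event$strand), ,
                 drop = FALSE]
  hit <- (cand$donor_pos %in% keys$pos[keys$side == "donor"]) |
    (cand$acceptor_pos %in% keys$pos[keys$side == "acceptor"])
  cand <- cand[hit, , drop = FALSE]
  lstar <- if (nrow(cand) > 0) max(cand$count) else 0
  partner <- c(donor_pos = NA_integer_, acceptor_pos = NA_integer_)
  if (nrow(cand) > 0 && lstar > 0) {
    best <- cand[cand$count == lstar, , drop = FALSE]
    best <- best[order(best$donor_pos, best$acceptor_pos), , drop = FALSE]
    partner <- c(donor_pos = best$donor_pos[1],
                 acceptor_pos = best$acceptor_pos[1])
  }
  if (lstar > 0 && bs_count > 0) {
    list(ratio = bs_count / lstar, status = "ok", linear_count = lstar,
         partner = partner)
  } else if (lstar > 0) {
    list(ratio = 0, status = "zero_circ", linear_count = lstar,
         partner = partner)
  } else if (bs_count > 0) {
    list(ratio = NA_real_, status = "no_linear_partner", linear_count = 0,
         partner = partner)
  } else {
    list(ratio = NA_real_, status = "both_zero", linear_count = 0,
         partner = partner)
  }
}

#' Circular-to-linear ratio matrix with group summaries
#'
#' Applies the [circ_lin_ratio()] rule to every event x sample cell of a
#' (filtered, normalized) junction count table, vectorized through a join
#' on donor/acceptor coordinates, and summarises ratios per group.
#'
#' @param table a [junction_count_table()].
#' @param linear linear junction tibble on the same normalization scale.
#' @param metadata sample metadata (`sample_id`, `group`).
#' @return list of class `circlin_ratio_matrix`: `ratio` (events x samples
#'   matrix, NA where undefined), `status` (character matrix), `events`,
#'   and `summary` (per event: group mean/median ratio over non-missing
#'   cells and the fraction of cells with status `ok`).
#' @export
ratio_matrix <- function(table, linear, metadata) {
  stopifnot(inherits(table, "junction_count_table"))
  assert_two_groups(metadata)
  events <- table$events
  samples <- colnames(table$counts)
  ne <- nrow(events); ns <- length(samples)
  lstar <- matrix(0, ne, ns, dimnames = list(events$event_id, samples))
  if (ne > 0 && nrow(linear) > 0) {
    keys <- event_match_keys(events$chrom, events$start, events$end,
                             events$strand)
    lin <- linear[linear$sample_id %in% samples, , drop = FALSE]
    dk <- keys[keys$side == "donor", ]
    ak <- keys[keys$side == "acceptor", ]
    hits_d <- dplyr::inner_join(
      lin, dk, by = c(chrom = "chrom", donor_pos = "pos"),
      relationship = "many-to-many")
    hits_a <- dplyr::inner_join(
      lin, ak, by = c(chrom = "chrom", acceptor_pos = "pos"),
      relationship = "many-to-many")
    hits <- dplyr::bind_rows(hits_d, hits_a)
    if (nrow(hits) > 0) {
      hits <- hits[strand_compatible(hits$strand,
                                     events$strand[hits$event_idx]), ,
                   drop = FALSE]
    }
    if (nrow(hits) > 0) {
      agg <- hits |>
        dplyr::group_by(.data$event_idx, .data$sample_id) |>
        dplyr::summarise(lstar = max(.data$count), .groups = "drop")
      lstar[cbind(agg$event_idx, match(agg$sample_id, samples))] <- agg$lstar
    }
  }
  bs <- table$counts
  ratio <- ifelse(lstar > 0, bs / lstar, NA_real_)
  ratio[lstar > 0 & bs == 0] <- 0
  status <- matrix("both_zero", ne, ns,
                   dimnames = list(events$event_id, samples))
  status[lstar > 0 & bs > 0] <- "ok"
  status[lstar > 0 & bs == 0] <- "zero_circ"
  status[lstar == 0 & bs > 0] <- "no_linear_partner"

  grp <- metadata$group[match(samples, metadata$sample_id)]
  summarise_group <- function(g) {
    sub <- ratio[, grp == g, drop = FALSE]
    tibble::tibble(
      mean = if (ne > 0) rowMeans(sub, na.rm = TRUE) else numeric(),
      median = if (ne > 0) apply(sub, 1, median, na.rm = TRUE) else numeric())
  }
  cs <- summarise_group("case"); ct <- summarise_group("control")
  summary <- tibble::tibble(
    event_id = events$event_id,
    mean_ratio_case = ifelse(is.nan(cs$mean), NA_real_, cs$mean),
    median_ratio_case = cs$median,
    mean_ratio_control = ifelse(is.nan(ct$mean), NA_real_, ct$mean),
    median_ratio_control = ct$median,
    frac_ok = if (ne > 0) rowMeans(status == "ok") else numeric())
  structure(list(ratio = ratio, status = status, events = events,
                 summary = summary),
            class = "circlin_ratio_matrix")
}

#' @export
print.circlin_ratio_matrix <- function(x, ...) {
  cat(sprintf("<circlin_ratio_matrix> %d events x %d samples; %.0f%% cells ok\n",
              nrow(x$ratio), ncol(x$ratio),
              100 * mean(x$status == "ok")))
  invisible(x)
}

#' Intersect events with an external candidate list
#'
#' Candidates may be given as event ids (`chrom:start|end`) and/or gene
#' ids; a gene-level key returns every back-splice isoform of that gene
#' (distinct circRNAs from one gene are tracked separately). Candidate ids
#' matching nothing are ignored (and reported in the attribute).
#'
#' @param events event tibble (from a [junction_count_table()]).
#' @param candidate_ids character vector of event and/or gene ids.
#' @return the matching subset of `events`, with a `match_key` column
#'   ("event_id" or "gene_id") and an `unmatched` attribute listing
#'   candidate ids that hit nothing.
#' @export
intersect_candidates <- function(events, candidate_ids) {
  candidate_ids <- unique(candidate_ids)
  by_event <- events$event_id %in% candidate_ids
  by_gene <- events$gene_id %in% candidate_ids & events$gene_id != ""
  out <- events[by_event | by_gene, , drop = FALSE]
  out$match_key <- ifelse(by_event[by_event | by_gene], "event_id", "gene_id")
  matched <- union(events$event_id[by_event], events$gene_id[by_gene])
  attr(out, "unmatched") <- setdiff(candidate_ids, matched)
  out
}
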