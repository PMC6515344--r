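# TSV readers/writers for every table the pipeline touches. All dialects are
# UTF-8 TSV with a mandatory header (except STAR SJ.out.tab, which has none
# upstream); "." and "NA" denote missing values. Lines starting with
# "#circlin" carry table-level attributes and survive round trips.

read_tsv_strict <- function(path, col_types = NULL, col_names = TRUE,
                            comment = "") {
  if (!file.exists(path)) {
    abort_circlin(paste0("file not found: ", path))
  }
  readr::read_tsv(path, col_types = col_types, col_names = col_names,
                  na = c("NA", "."), comment = comment,
                  progress = FALSE, show_col_types = FALSE)
}

require_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort_circlin(sprintf("%s: missing required column(s): %s", what,
                          paste(missing_cols, collapse = ", ")),
                  class = "circlin_format_error")
  }
  invisible(df)
}

#' Read one CIRI2 back-splice table for one sample
#'
#' Consumes the CIRI2 output dialect: a TSV whose required columns are
#' `circRNA_ID`, `chr`, `circRNA_start`, `circRNA_end`, `#junction_reads`
#' (accepted also as `junction_reads`), `strand`, and `gene_id`; extra
#' columns are ignored. The event id is re-derived from the coordinates as
#' `chrom:start|end` and checked against `circRNA_ID`; on mismatch the
#' coordinates win with a warning. Duplicate rows for one
#' (chrom, start, end, strand) have their junction reads summed, with a
#' warning (summing is lossless; CIRI2 should not emit them).
#'
#' @param path TSV file path.
#' @param sample_id sample label to attach to every record.
#' @return tibble: `event_id`, `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `sample_id`, `count`.
#' @export
read_ciri_table <- function(path, sample_id) {
  df <- read_tsv_strict(path)
  if ("#junction_reads" %in% names(df) && !"junction_reads" %in% names(df)) {
    names(df)[names(df) == "#junction_reads"] <- "junction_reads"
  }
  require_columns(df, c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                        "junction_reads", "strand", "gene_id"),
                  "CIRI2 table")
  if (nrow(df) > 0 && any(df$junction_reads < 0, na.rm = TRUE)) {
    abort_circlin("CIRI2 table: negative junction read count",
                  class = "circlin_format_error")
  }
  out <- tibble::tibble(
    chrom = as.character(df$chr),
    start = as.integer(df$circRNA_start),
    end = as.integer(df$circRNA_end),
    strand = as.character(df$strand),
    gene_id = ifelse(is.na(df$gene_id), "", as.character(df$gene_id)),
    sample_id = sample_id,
    count = as.numeric(df$junction_reads))
  out$event_id <- make_event_id(out$chrom, out$start, out$end)
  mismatch <- !is.na(df$circRNA_ID) & df$circRNA_ID != out$event_id
  if (any(mismatch)) {
    warning(sprintf(
      "%d circRNA_ID value(s) disagree with coordinates; coordinates used",
      sum(mismatch)), call. = FALSE)
  }
  key <- paste(out$chrom, out$start, out$end, out$strand)
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate back-splice row(s) summed",
                    sum(duplicated(key))), call. = FALSE)
    out <- out |>
      dplyr::group_by(.data$event_id, .data$chrom, .data$start, .data$end,
                      .data$strand, .data$gene_id, .data$sample_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  out[c("event_id", "chrom", "start", "end", "strand", "gene_id",
        "sample_id", "count")]
}

#' Merge per-sample back-splice records into one count table
#'
#' Takes the union of events across samples (an event absent from a sample
#' gets count 0) and orders events deterministically by
#' (chrom, start, end, strand), independent of input row order.
#'
#' @param sample_tables list of per-sample record tibbles as returned by
#'   [read_ciri_table()] (or a single tibble covering several samples).
#' @param lib_sizes named vector of per-sample library sizes.
#' @return a raw-count [junction_count_table()].
#' @export
merge_sample_tables <- function(sample_tables, lib_sizes) {
  if (is.data.frame(sample_tables)) sample_tables <- list(sample_tables)
  if (length(sample_tables) < 1) abort_circlin("need at least one sample")
  recs <- dplyr::bind_rows(sample_tables)
  per_sample <- lapply(sample_tables, function(x) unique(x$sample_id))
  flat <- unlist(per_sample)
  if (anyDuplicated(flat)) {
    abort_circlin(paste0("duplicate sample id(s): ",
                         paste(unique(flat[duplicated(flat)]), collapse = ", ")))
  }
  samples <- flat
  events <- recs |>
    dplyr::distinct(.data$event_id, .data$chrom, .data$start, .data$end,
                    .data$strand, .keep_all = TRUE) |>
    dplyr::select("event_id", "chrom", "start", "end", "strand", "gene_id")
  events <- order_events(events)
  counts <- matrix(0, nrow = nrow(events), ncol = length(samples),
                   dimnames = list(events$event_id, samples))
  idx <- cbind(match(recs$event_id, events$event_id),
               match(recs$sample_id, samples))
  counts[idx] <- recs$count
  junction_count_table(events, counts, lib_sizes = lib_sizes)
}

#' Read a linear splice-junction table
#'
#' Two dialects:
#' * `generic`: headered TSV with columns `chrom`, `donor_pos`,
#'   `acceptor_pos`, `strand`, `sample_id`, `count`;
#' * `star_sj`: STAR `SJ.out.tab` (no header; columns chrom, intron start,
#'   intron end, strand code 0/1/2, motif, annotated, unique reads,
#'   multi-mapping reads). Donor/acceptor are the flanking exonic bases
#'   (`donor = intron_start - 1`, `acceptor = intron_end + 1`), the strand
#'   code maps 1 to `+`, 2 to `-`, 0 to `.`, and the unique-read column is
#'   used as the count (multi-mappers ignored).
#'
#' @param path TSV path.
#' @param dialect `"generic"` or `"star_sj"`.
#' @param sample_id required for `star_sj` (the file carries no sample
#'   column).
#' @return tibble in the generic schema.
#' @export
read_linear_junctions <- function(path, dialect = c("generic", "star_sj"),
                                  sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "generic") {
    df <- read_tsv_strict(path, comment = "#circlin")
    require_columns(df, c("chrom", "donor_pos", "acceptor_pos", "strand",
                          "sample_id", "count"), "linear junction table")
    out <- tibble::tibble(
      chrom = as.character(df$chrom),
      donor_pos = as.integer(df$donor_pos),
      acceptor_pos = as.integer(df$acceptor_pos),
      strand = as.character(df$strand),
      sample_id = as.character(df$sample_id),
      count = as.integer(df$count))
  } else {
    if (is.null(sample_id)) {
      abort_circlin("star_sj dialect needs an explicit sample_id")
    }
    df <- read_tsv_strict(path, col_names = FALSE)
    if (ncol(df) < 8) {
      abort_circlin("SJ.out.tab: expected at least 8 columns",
                    class = "circlin_format_error")
    }
    code <- as.integer(df[[4]])
    if (nrow(df) > 0 && any(!code %in% 0:2)) {
      abort_circlin("SJ.out.tab: malformed strand code (must be 0/1/2)",
                    class = "circlin_format_error")
    }
    out <- tibble::tibble(
      chrom = as.character(df[[1]]),
      donor_pos = as.integer(df[[2]]) - 1L,
      acceptor_pos = as.integer(df[[3]]) + 1L,
      strand = c(".", "+", "-")[code + 1L],
      sample_id = sample_id,
      count = as.integer(df[[7]]))
  }
  if (nrow(out) > 0 && any(out$count < 0, na.rm = TRUE)) {
    abort_circlin("negative linear junction count",
                  class = "circlin_format_error")
  }
  if (nrow(out) > 0 && any(out$donor_pos == out$acceptor_pos)) {
    abort_circlin("linear junction with donor_pos == acceptor_pos",
                  class = "circlin_format_error")
  }
  out
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `group` (labels `case` / `control`),
#' `mrc_megascore` (real or missing), `mirs_stage` (integer 1-5 or
#' missing); extra columns pass through untouched.
#'
#' @param path TSV path.
#' @return metadata tibble.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_strict(path, comment = "#circlin")
  require_columns(df, c("sample_id", "group"), "metadata")
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample_id)) {
    abort_circlin("duplicate sample ids in metadata")
  }
  assert_two_groups(df)
  if (!"mrc_megascore" %in% names(df)) df$mrc_megascore <- NA_real_
  if (!"mirs_stage" %in% names(df)) df$mirs_stage <- NA_integer_
  df$mrc_megascore <- as.numeric(df$mrc_megascore)
  df$mirs_stage <- as.integer(df$mirs_stage)
  bad <- !is.na(df$mirs_stage) & !(df$mirs_stage %in% 1:5)
  if (any(bad)) abort_circlin("mirs_stage must be in 1..5 or missing")
  tibble::as_tibble(df)
}

#' Read a long-format qPCR Ct table
#'
#' TSV with columns `target_id`, `isoform` (circular/linear/reference),
#' `sample_id`, `ct`, and optionally `replicate`. Records with missing or
#' non-numeric Ct are dropped with a warning (never imputed); Ct values
#' outside the plausibility window are rejected.
#'
#' @param path TSV path.
#' @param ct_window plausible Ct range, cycles (default `c(5, 40)`).
#' @return Ct tibble.
#' @export
read_ct_table <- function(path, ct_window = c(5, 40)) {
  df <- read_tsv_strict(path, comment = "#circlin")
  require_columns(df, c("target_id", "isoform", "sample_id", "ct"),
                  "Ct table")
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df$replicate <- as.integer(df$replicate)
  suppressWarnings(ct_num <- as.numeric(df$ct))
  drop <- is.na(ct_num)
  if (any(drop)) {
    warning(sprintf("dropped %d Ct record(s) with missing/non-numeric Ct",
                    sum(drop)), call. = FALSE)
    df <- df[!drop, , drop = FALSE]
    ct_num <- ct_num[!drop]
  }
  df$ct <- ct_num
  if (!all(df$isoform %in% c("circular", "linear", "reference"))) {
    abort_circlin("isoform must be circular/linear/reference")
  }
  if (nrow(df) > 0 &&
      any(df$ct < ct_window[1] | df$ct > ct_window[2])) {
    abort_circlin(sprintf("Ct value(s) outside plausible window [%g, %g]",
                          ct_window[1], ct_window[2]))
  }
  if (anyDuplicated(df[c("target_id", "isoform", "sample_id", "replicate")])) {
    abort_circlin("duplicate (target, isoform, sample, replicate) records")
  }
  tibble::as_tibble(df[c("target_id", "isoform", "sample_id", "replicate",
                         "ct")])
}

#' Read an RT-PCR splicing band/percentage table
#'
#' TSV with columns `event_name`, `direction` (exclusion/inclusion),
#' `sample_id`, `incl_intensity`, `excl_intensity`, and optionally
#' `percent`. When `percent` is missing both intensities must not be zero.
#'
#' @param path TSV path.
#' @return splicing tibble.
#' @export
read_splicing_table <- function(path) {
  df <- read_tsv_strict(path, comment = "#circlin")
  require_columns(df, c("event_name", "direction", "sample_id",
                        "incl_intensity", "excl_intensity"),
                  "splicing table")
  if (!"percent" %in% names(df)) df$percent <- NA_real_
  if (!all(df$direction %in% c("exclusion", "inclusion"))) {
    abort_circlin("direction must be 'exclusion' or 'inclusion'")
  }
  if (nrow(df) > 0 &&
      any(df$incl_intensity < 0 | df$excl_intensity < 0, na.rm = TRUE)) {
    abort_circlin("band intensities must be non-negative")
  }
  both_zero <- df$incl_intensity == 0 & df$excl_intensity == 0 &
    is.na(df$percent)
  if (any(both_zero, na.rm = TRUE)) {
    abort_circlin("both band intensities zero with percent missing")
  }
  tibble::as_tibble(df[c("event_name", "direction", "sample_id",
                         "incl_intensity", "excl_intensity", "percent")])
}

schema_line <- function(kind) sprintf("#circlin %s v1", kind)

write_with_schema <- function(df, path, kind, extra = character()) {
  con <- file(path, open = "wb")       # binary mode: LF on every platform
  on.exit(close(con))
  writeLines(c(schema_line(kind), extra), con, sep = "\n")
  writeChar(readr::format_tsv(tibble::as_tibble(df), na = "."), con,
            eos = NULL)
  invisible(path)
}

#' Write / read a junction count table (round-trip exact)
#'
#' The TSV carries the event columns followed by one column per sample;
#' `#circlin` header lines record the normalization flag and library sizes.
#'
#' @param table a [junction_count_table()].
#' @param path output TSV path.
#' @return `path`, invisibly (writer); a [junction_count_table()] (reader).
#' @export
write_junction_table <- function(table, path) {
  stopifnot(inherits(table, "junction_count_table"))
  wide <- dplyr::bind_cols(table$events,
                           tibble::as_tibble(table$counts, .name_repair = "minimal"))
  extra <- sprintf("#circlin normalized=%s", table$normalized)
  if (!is.null(table$lib_sizes)) {
    extra <- c(extra, sprintf("#circlin lib_sizes=%s",
                              paste(sprintf("%s:%.0f", names(table$lib_sizes),
                                            table$lib_sizes), collapse = ",")))
  }
  write_with_schema(wide, path, "junction_counts", extra)
}

#' @rdname write_junction_table
#' @export
read_junction_table <- function(path) {
  header <- readLines(path, n = 10)
  header <- header[startsWith(header, "#circlin")]
  normalized <- any(grepl("normalized=TRUE", header, fixed = TRUE))
  lib_sizes <- NULL
  ls_line <- grep("lib_sizes=", header, value = TRUE)
  if (length(ls_line) == 1) {
    spec_str <- sub(".*lib_sizes=", "", ls_line)
    parts <- strsplit(strsplit(spec_str, ",")[[1]], ":")
    lib_sizes <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    names(lib_sizes) <- vapply(parts, `[`, character(1), 1)
  }
  df <- read_tsv_strict(path, comment = "#circlin")
  require_columns(df, c("event_id", "chrom", "start", "end", "strand",
                        "gene_id"), "junction count table")
  sample_cols <- setdiff(names(df), c("event_id", "chrom", "start", "end",
                                      "strand", "gene_id"))
  events <- df[c("event_id", "chrom", "start", "end", "strand", "gene_id")]
  events$start <- as.integer(events$start)
  events$end <- as.integer(events$end)
  events$gene_id <- ifelse(is.na(events$gene_id), "", events$gene_id)
  counts <- as.matrix(df[sample_cols])
  junction_count_table(events, counts, lib_sizes = lib_sizes,
                       normalized = normalized)
}

#' Write any long-format circlin table with its schema line
#'
#' @param df tibble to write.
#' @param path output path.
#' @param kind schema tag (e.g. "linear_junctions", "metadata", "ct",
#'   "splicing", "results").
#' @return `path`, invisibly.
#' @export
write_circlin_tsv <- function(df, path, kind) {
  write_with_schema(df, path, kind)
}

#' Write pipeline result tables plus a JSON run manifest
#'
#' Emits one TSV per result component (schema-versioned) and a
#' `manifest.json` holding the configuration snapshot, seed, stage row
#' counts and an md5 digest of every written file.
#'
#' @param results named list of tibbles/data frames to write.
#' @param dir output directory (created if needed).
#' @param manifest named list of run metadata (config, seed, counts).
#' @return named vector of written file paths, invisibly.
#' @export
write_results <- function(results, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_with_schema(tibble::as_tibble(results[[nm]]), p,
                      kind = paste0("results/", nm))
    paths[nm] <- p
  }
  manifest$files <- lapply(paths, function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p))))
  manifest$schema <- "circlin/1"
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["manifest"] <- mpath
  invisible(paths)
}
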