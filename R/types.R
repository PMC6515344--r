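#' Junction count table
#'
#' Container pairing a set of back-splice events with an events x samples
#' count matrix. Counts are either raw junction reads (with per-sample
#' library sizes) or counts-per-million after [normalize_per_million()].
#'
#' @param events tibble with columns `event_id`, `chrom`, `start`, `end`,
#'   `strand`, `gene_id`. Coordinates are 1-based inclusive; `start` is the
#'   first base of the circRNA (acceptor side on the + strand) and `end` the
#'   last (donor side on the + strand). `strand` is one of `+`, `-`, `.`.
#' @param counts numeric matrix, `nrow(events)` x number of samples, with
#'   sample ids as column names. No negative entries.
#' @param lib_sizes named vector of per-sample library sizes (total reads);
#'   required while `normalized = FALSE`.
#' @param normalized logical; `TRUE` once counts are per-million scaled.
#' @return an object of class `junction_count_table`.
#' @export
junction_count_table <- function(events, counts, lib_sizes = NULL,
                                 normalized = FALSE) {
  events <- tibble::as_tibble(events)
  required <- c("event_id", "chrom", "start", "end", "strand", "gene_id")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort_circlin(paste0("events table missing column(s): ",
                         paste(missing_cols, collapse = ", ")))
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(events)) {
    abort_circlin("counts must have one row per event")
  }
  if (is.null(colnames(counts))) {
    abort_circlin("counts must carry sample ids as column names")
  }
  if (nrow(counts) > 0 && ncol(counts) > 0 && any(counts < 0, na.rm = TRUE)) {
    abort_circlin("negative junction counts are not allowed")
  }
  if (anyDuplicated(events[c("chrom", "start", "end", "strand")])) {
    abort_circlin("duplicate (chrom, start, end, strand) events in table")
  }
  bad <- events$start > events$end
  if (any(bad)) abort_circlin("event start must be <= end")
  if (!normalized) {
    if (is.null(lib_sizes)) {
      abort_circlin("lib_sizes required for raw (non-normalized) counts")
    }
    missing_ls <- setdiff(colnames(counts), names(lib_sizes))
    if (length(missing_ls) > 0) {
      abort_circlin(paste0("lib_sizes missing for sample(s): ",
                           paste(missing_ls, collapse = ", ")))
    }
    if (any(lib_sizes[colnames(counts)] <= 0)) {
      abort_circlin("library sizes must be positive")
    }
  }
  rownames(counts) <- events$event_id
  structure(
    list(events = events, counts = counts,
         lib_sizes = if (is.null(lib_sizes)) NULL else
           lib_sizes[intersect(names(lib_sizes), colnames(counts))],
         normalized = isTRUE(normalized)),
    class = "junction_count_table")
}

#' @export
print.junction_count_table <- function(x, ...) {
  cat(sprintf("<junction_count_table> %d events x %d samples (%s)\n",
              nrow(x$events), ncol(x$counts),
              if (x$normalized) "counts per million" else "raw counts"))
  invisible(x)
}

#' @export
dim.junction_count_table <- function(x) dim(x$counts)

#' Event donor/acceptor genomic coordinates
#'
#' For a back-splice on the + strand the donor site is the event end and the
#' acceptor the event start; the roles swap on the - strand. Events with
#' unknown strand (".") expose both coordinates on both sides so linear
#' junctions can match in either orientation.
#'
#' @param chrom,start,end,strand event fields (vectorized over events).
#' @return tibble with one row per (event, side, position) matching key:
#'   columns `event_idx`, `chrom`, `side` ("donor"/"acceptor"), `pos`.
#' @keywords internal
event_match_keys <- function(chrom, start, end, strand) {
  n <- length(chrom)
  if (n == 0) {
    return(tibble::tibble(event_idx = integer(), chrom = character(),
                          side = character(), pos = integer()))
  }
  idx <- seq_len(n)
  donor <- ifelse(strand == "-", start, end)
  acceptor <- ifelse(strand == "-", end, start)
  keys <- dplyr::bind_rows(
    tibble::tibble(event_idx = idx, chrom = chrom, side = "donor",
                   pos = as.integer(donor)),
    tibble::tibble(event_idx = idx, chrom = chrom, side = "acceptor",
                   pos = as.integer(acceptor)))
  dot <- strand == "."
  if (any(dot)) {
    keys <- dplyr::bind_rows(
      keys,
      tibble::tibble(event_idx = idx[dot], chrom = chrom[dot], side = "donor",
                     pos = as.integer(start[dot])),
      tibble::tibble(event_idx = idx[dot], chrom = chrom[dot],
                     side = "acceptor", pos = as.integer(end[dot])))
  }
  dplyr::distinct(keys)
}
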