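# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Each simulated table draws from its own stream so that, e.g., regenerating
#' only the Ct matrix does not perturb the junction counts. The derived seed
#' stays within the 32-bit integer range R requires.
#'
#' @param seed master integer seed.
#' @param label character tag naming the stream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647L)
}

abort_circlin <- function(msg, class = "circlin_error") {
  rlang::abort(msg, class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical rendering of a back-splice event id
make_event_id <- function(chrom, start, end) {
  sprintf("%s:%d|%d", chrom, as.integer(start), as.integer(end))
}

# deterministic event ordering: chrom (natural-ish), start, end, strand
order_events <- function(events) {
  events[order(events$chrom, events$start, events$end, events$strand), ,
         drop = FALSE]
}

assert_two_groups <- function(metadata) {
  groups <- unique(metadata$group)
  if (!all(groups %in% c("case", "control"))) {
    abort_circlin(sprintf(
      "unknown group label(s): %s (expected 'case'/'control')",
      paste(setdiff(groups, c("case", "control")), collapse = ", ")))
  }
  invisible(metadata)
}
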