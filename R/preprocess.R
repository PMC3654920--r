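#' Preprocessing parameters (adapter trimming + quality filter)
#'
#' The published pipeline preprocessed reads with FASTX-Toolkit; the exact
#' thresholds are not recoverable, so these defaults are conventional and
#' everything is configurable.
#'
#' @param adapter 3' adapter sequence to trim.
#' @param min_overlap Minimum adapter/read overlap (nt) for a 3'-terminal
#'   partial match.
#' @param max_adapter_mismatch_rate Tolerated mismatch rate within the
#'   matched adapter bases (cutadapt-style, default 0.1).
#' @param q_threshold Phred score counted as "good".
#' @param min_fraction_above_q Minimum fraction of bases with Phred >=
#'   `q_threshold` (boundary inclusive).
#' @param min_insert_len,max_insert_len Post-trim length bounds (nt).
#' @return A `preprocess_params` object.
#' @export
preprocess_params <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                              min_overlap = 5L,
                              max_adapter_mismatch_rate = 0.1,
                              q_threshold = 20L,
                              min_fraction_above_q = 0.8,
                              min_insert_len = 5L, max_insert_len = 48L) {
  stopifnot(min_overlap > 0L, min_overlap <= nchar(adapter),
            max_adapter_mismatch_rate >= 0, max_adapter_mismatch_rate <= 1,
            min_fraction_above_q >= 0, min_fraction_above_q <= 1)
  structure(list(adapter = adapter, min_overlap = as.integer(min_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate,
                 q_threshold = as.integer(q_threshold),
                 min_fraction_above_q = min_fraction_above_q,
                 min_insert_len = as.integer(min_insert_len),
                 max_insert_len = as.integer(max_insert_len)),
            class = "preprocess_params")
}

#' Trim the 3' adapter from read sequences
#'
#' Removes the leftmost adapter occurrence — the full adapter anywhere in the
#' read, or a 3'-terminal prefix of the adapter of at least `min_overlap`
#' bases — together with everything 3' of it, tolerating a mismatch rate of
#' `max_adapter_mismatch_rate` over the matched bases. Reads without an
#' adapter occurrence are returned unchanged; trimming is total (a read can
#' trim to the empty string) and idempotent.
#'
#' @param seqs Character vector of read sequences.
#' @param params A [preprocess_params()].
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(seqs, params = preprocess_params()) {
  keep <- .adapter_keep_len(seqs, params$adapter, params$min_overlap,
                            params$max_adapter_mismatch_rate)
  substr(seqs, 1L, keep)
}

#' Quality + length filter
#'
#' Keep a read iff the fraction of bases with Phred >= `q_threshold` is at
#' least `min_fraction_above_q` (computed on the insert's quality string) and
#' the insert length is within `[min_insert_len, max_insert_len]`.
#'
#' @param seqs,quals Equal-length character vectors (insert sequence and its
#'   Phred+33 quality string, same per-read lengths).
#' @param params A [preprocess_params()].
#' @return Logical vector: keep?
#' @export
quality_filter <- function(seqs, quals, params = preprocess_params()) {
  if (any(nchar(seqs) != nchar(quals))) {
    abort("sequence and quality strings differ in length",
          class = "trnahalves_format_error")
  }
  len_ok <- nchar(seqs) >= params$min_insert_len &
    nchar(seqs) <= params$max_insert_len
  uq <- unique(quals)  # quality strings are highly duplicated in practice
  uq_ok <- vapply(uq, function(q) {
    if (!nchar(q)) return(FALSE)
    ph <- utf8ToInt(q) - 33L
    mean(ph >= params$q_threshold) >= params$min_fraction_above_q
  }, logical(1), USE.NAMES = FALSE)
  len_ok & uq_ok[match(quals, uq)]
}

#' Preprocess a read table: trim adapters, then filter
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param params A [preprocess_params()].
#' @return List with `reads` (surviving tibble, trimmed `seq`/`qual`) and
#'   `log` (one-row tibble: reads in, with adapter trimmed, discarded by
#'   quality, discarded by length, reads out).
#' @export
preprocess_reads <- function(reads, params = preprocess_params()) {
  n_in <- nrow(reads)
  trimmed <- trim_adapter(reads$seq, params)
  n_trimmed <- sum(nchar(trimmed) < nchar(reads$seq))
  quals <- substr(reads$qual, 1L, nchar(trimmed))
  len_ok <- nchar(trimmed) >= params$min_insert_len &
    nchar(trimmed) <= params$max_insert_len
  q_ok <- quality_filter(trimmed, quals,
                         # length screening handled separately for the log
                         preprocess_params(
                           adapter = params$adapter,
                           min_overlap = params$min_overlap,
                           max_adapter_mismatch_rate = params$max_adapter_mismatch_rate,
                           q_threshold = params$q_threshold,
                           min_fraction_above_q = params$min_fraction_above_q,
                           min_insert_len = 0L, max_insert_len = .Machine$integer.max))
  keep <- len_ok & q_ok
  out <- reads
  out$seq <- trimmed
  out$qual <- quals
  list(reads = out[keep, , drop = FALSE],
       log = tibble(n_in = n_in, n_trimmed = n_trimmed,
                    n_discarded_quality = sum(len_ok & !q_ok),
                    n_discarded_length = sum(!len_ok),
                    n_out = sum(keep)))
}
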