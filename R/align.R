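#' Alignment policy
#'
#' The two policies whose contrast drives the analysis:
#' * `maq_like` — candidate placements come from an exact match of the
#'   read's first `seed_len` bases (the high-quality 5' end), extended
#'   end-to-end with at most `max_total_mismatches` mismatches overall.
#' * `kdiff` — end-to-end k-difference: every placement with at most `v`
#'   mismatches anywhere in the read.
#'
#' @param mode `"maq_like"` or `"kdiff"`.
#' @param seed_len Seed length in nt (default 14).
#' @param seed_mismatches Mismatches allowed inside the seed (default 0; a
#'   positive value routes through the exhaustive-scan path, which is exact
#'   but slower).
#' @param max_total_mismatches Total mismatch budget for `maq_like`.
#' @param v Mismatch budget for `kdiff`.
#' @return An `align_policy` object.
#' @export
align_policy <- function(mode = c("maq_like", "kdiff"), seed_len = 14L,
                         seed_mismatches = 0L, max_total_mismatches = 2L,
                         v = 0L) {
  mode <- match.arg(mode)
  stopifnot(seed_len >= 4L, seed_mismatches >= 0L,
            max_total_mismatches >= 0L, v >= 0L)
  structure(list(mode = mode, seed_len = as.integer(seed_len),
                 seed_mismatches = as.integer(seed_mismatches),
                 max_total_mismatches = as.integer(max_total_mismatches),
                 v = as.integer(v)),
            class = "align_policy")
}

# Chromosomes are concatenated with runs of N longer than any read, so one
# C++ scan covers the genome; placements are then mapped back to (chrom, pos)
# and any touching a separator dropped.
SEP_LEN <- 64L

#' Build an exact-match seed index over a genome
#'
#' A hash from every `seed_len`-mer of the forward genome to its positions.
#' [index_lookup()] resolves a query k-mer on both strands (a minus-strand
#' occurrence is a forward occurrence of the reverse complement).
#'
#' @param ref A `trna_reference`, or a named character vector of chromosome
#'   sequences.
#' @param seed_len K-mer length (>= 4).
#' @return A `trna_index` holding the hash, the concatenated subject and the
#'   chromosome offsets.
#' @export
build_index <- function(ref, seed_len = 14L) {
  if (inherits(ref, "trna_reference")) ref <- ref$genome
  stopifnot(is.character(ref), !is.null(names(ref)))
  seed_len <- as.integer(seed_len)
  if (seed_len < 4L) {
    abort("seed_len must be >= 4", class = "trnahalves_parameter_error")
  }
  sep <- strrep("N", SEP_LEN)
  subject <- paste(ref, collapse = sep)
  sizes <- nchar(ref)
  offsets <- cumsum(c(0L, head(sizes + SEP_LEN, -1L)))  # 0-based global starts
  names(offsets) <- names(ref)

  kmers <- character(0)
  pos <- integer(0)
  for (i in seq_along(ref)) {
    L <- sizes[i]
    if (L < seed_len) next
    n <- L - seed_len + 1L
    kmers <- c(kmers, substring(ref[i], seq_len(n), seq_len(n) + seed_len - 1L))
    pos <- c(pos, offsets[i] + seq_len(n))  # 1-based global position
  }
  hash <- list2env(split(pos, kmers), hash = TRUE, size = length(pos))
  structure(list(hash = hash, subject = subject, seed_len = seed_len,
                 chrom_names = names(ref), chrom_sizes = sizes,
                 offsets = offsets),
            class = "trna_index")
}

#' @export
print.trna_index <- function(x, ...) {
  cat("<trna_index> seed_len=", x$seed_len, ", ",
      length(x$chrom_names), " chromosomes, ", sum(x$chrom_sizes),
      " bp\n", sep = "")
  invisible(x)
}

# 1-based global position -> (chrom, 0-based chrom-local start); NA chrom for
# placements that cross a separator.
decode_global <- function(index, gpos, len) {
  i <- findInterval(gpos, index$offsets + 1L)
  start_local <- gpos - index$offsets[i] - 1L
  ok <- start_local >= 0L & start_local + len <= index$chrom_sizes[i]
  tibble(chrom = ifelse(ok, index$chrom_names[i], NA_character_),
         start = ifelse(ok, start_local, NA_integer_))
}

#' Look up all genomic occurrences of a k-mer
#'
#' @param index A `trna_index`.
#' @param kmer A string of length `index$seed_len`.
#' @return Tibble of `chrom`, `start` (0-based), `strand` for every exact
#'   occurrence on either strand; zero rows when absent.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$seed_len)
  k <- index$seed_len
  fwd <- index$hash[[kmer]]
  rev <- index$hash[[revcomp(kmer)]]
  out <- list()
  if (!is.null(fwd)) {
    out[[1]] <- decode_global(index, fwd, k) %>% mutate(strand = "+")
  }
  if (!is.null(rev)) {
    out[[2]] <- decode_global(index, rev, k) %>% mutate(strand = "-")
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), strand = character()))
  }
  bind_rows(out) %>% filter(!is.na(.data$chrom)) %>%
    arrange(.data$chrom, .data$start, .data$strand)
}

# Valid placements of one query sequence in global coordinates:
# list(gstart (1-based global), strand, mm), placements crossing chromosome
# separators already removed; NULL when none. `rc` is the precomputed
# reverse complement (batched in align_reads for speed).
align_seq_core <- function(seq, rc, index, policy) {
  n <- nchar(seq)
  k <- index$seed_len
  gstart <- integer(0); strand <- character(0); mm_out <- integer(0)
  scan_path <- policy$mode == "kdiff" ||
    (policy$mode == "maq_like" && policy$seed_mismatches > 0L)
  for (qs in c("+", "-")) {
    q <- if (qs == "+") seq else rc
    soff <- if (qs == "+") 0L else n - k
    if (scan_path) {
      budget <- if (policy$mode == "kdiff") policy$v else policy$max_total_mismatches
      sc <- .scan_mismatch(index$subject, q, budget)
      if (!length(sc$start)) next
      starts <- sc$start
      mm <- sc$mm
      keep <- in_one_chrom(index, starts, n)
      if (policy$mode == "maq_like" && any(keep)) {
        seedq <- substr(q, soff + 1L, soff + k)
        smm <- .mismatch_at(index$subject, seedq, starts + soff)
        keep <- keep & !is.na(smm) & smm <= policy$seed_mismatches
      }
    } else {
      if (n < k) return(NULL)
      cand <- index$hash[[substr(q, soff + 1L, soff + k)]]
      if (is.null(cand)) next
      starts <- cand - soff  # 1-based global read start
      mm <- .mismatch_at(index$subject, q, starts)
      keep <- !is.na(mm) & mm <= policy$max_total_mismatches &
        in_one_chrom(index, starts, n)
    }
    if (any(keep)) {
      gstart <- c(gstart, starts[keep])
      strand <- c(strand, rep(qs, sum(keep)))
      mm_out <- c(mm_out, mm[keep])
    }
  }
  if (!length(gstart)) return(NULL)
  list(gstart = gstart, strand = strand, mm = mm_out)
}

# Does a read of length `len` starting at 1-based global position sit inside
# a single chromosome (not a separator)?
in_one_chrom <- function(index, gpos, len) {
  i <- findInterval(gpos, index$offsets + 1L)
  local <- gpos - index$offsets[i] - 1L
  local >= 0L & local + len <= index$chrom_sizes[i]
}

#' Align one read, returning its full valid set
#'
#' @param read Read sequence (a string).
#' @param index A [build_index()] result over the target genome.
#' @param policy An [align_policy()].
#' @param read_id Identifier carried into the result.
#' @return Tibble of `read_id`, `chrom`, `start` (0-based), `strand`,
#'   `n_mismatch`, `n_valid` — one row per valid placement, `n_valid` the
#'   exact total count. Reads shorter than the seed under `maq_like` yield
#'   zero rows.
#' @export
align_read <- function(read, index, policy = align_policy(), read_id = "read") {
  empty <- tibble(read_id = character(), chrom = character(), start = integer(),
                  strand = character(), n_mismatch = integer(),
                  n_valid = integer())
  if (policy$mode == "maq_like" && nchar(read) < index$seed_len) {
    return(structure(empty, skipped = read_id))
  }
  hits <- align_seq_core(read, revcomp(read), index, policy)
  if (is.null(hits)) return(empty)
  dec <- decode_global(index, hits$gstart, nchar(read))
  tibble(read_id = read_id, chrom = dec$chrom, start = dec$start,
         strand = hits$strand, n_mismatch = hits$mm,
         n_valid = length(hits$gstart)) %>%
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Align a table of reads (deduplicating identical sequences)
#'
#' @param reads Tibble with columns `read_id` and `seq`.
#' @inheritParams align_read
#' @return Tibble as in [align_read()], all reads combined. Reads with no
#'   valid placement are absent.
#' @export
align_reads <- function(reads, index, policy = align_policy()) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  useq <- unique(reads$seq)
  rc_useq <- revcomp(useq)
  per_seq <- vector("list", length(useq))
  for (i in seq_along(useq)) {
    if (policy$mode == "maq_like" && nchar(useq[i]) < index$seed_len) next
    per_seq[[i]] <- align_seq_core(useq[i], rc_useq[i], index, policy)
  }
  nhit <- vapply(per_seq, function(h) if (is.null(h)) 0L else length(h$gstart),
                 integer(1))
  keep <- which(nhit > 0L)
  if (!length(keep)) {
    return(tibble(read_id = character(), chrom = character(), start = integer(),
                  strand = character(), n_mismatch = integer(),
                  n_valid = integer()))
  }
  tab_seq <- rep(useq[keep], nhit[keep])
  gstart <- unlist(lapply(per_seq[keep], `[[`, "gstart"), use.names = FALSE)
  strand <- unlist(lapply(per_seq[keep], `[[`, "strand"), use.names = FALSE)
  mm <- unlist(lapply(per_seq[keep], `[[`, "mm"), use.names = FALSE)
  dec <- decode_global(index, gstart, nchar(tab_seq))
  tab <- tibble(seq = tab_seq, chrom = dec$chrom, start = dec$start,
                strand = strand, n_mismatch = mm,
                n_valid = rep(nhit[keep], nhit[keep])) %>%
    arrange(.data$seq, .data$chrom, .data$start, .data$strand)
  reads %>% select("read_id", "seq") %>%
    inner_join(tab, by = "seq", relationship = "many-to-many") %>%
    select(-"seq")
}

#' Apply a multiread reporting policy
#'
#' * `best_one` — exactly one placement per read: fewest mismatches, ties
#'   broken deterministically by (chrom, start, strand) or, with
#'   `tie_break = "random"`, uniformly at random among the tied best.
#' * `unique_only` — a read is reported only if its valid set has exactly
#'   one placement; multireads are suppressed entirely.
#'
#' @param alignments Output of [align_reads()] (full valid sets).
#' @param mode `"best_one"` or `"unique_only"`.
#' @param tie_break `"lexicographic"` (default) or `"random"`.
#' @return Tibble of reported alignments, one row per reported read,
#'   `n_valid` preserved.
#' @export
report_alignments <- function(alignments, mode = c("best_one", "unique_only"),
                              tie_break = c("lexicographic", "random")) {
  mode <- match.arg(mode)
  tie_break <- match.arg(tie_break)
  if (!nrow(alignments)) return(alignments)
  if (mode == "unique_only") {
    return(filter(alignments, .data$n_valid == 1L))
  }
  al <- if (tie_break == "random") {
    alignments %>% mutate(.r = runif(dplyr::n())) %>%
      arrange(.data$read_id, .data$n_mismatch, .data$.r) %>% select(-".r")
  } else {
    alignments %>%
      arrange(.data$read_id, .data$n_mismatch, .data$chrom, .data$start,
              .data$strand)
  }
  al %>% filter(!duplicated(.data$read_id))
}

#' Write reported alignments as minimal SAM
#'
#' Emits `@HD`/`@SQ` headers, FLAG 0/16 for strand, full-length match CIGAR,
#' an `NM` tag with the mismatch count and an `NH` tag with the size of the
#' read's valid set.
#'
#' @param alignments Reported alignments carrying a `seq` column (join the
#'   read table if needed).
#' @param index The `trna_index` (for `@SQ` lines).
#' @param path Output path.
#' @export
write_sam <- function(alignments, index, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con, sep = "\n")
  writeLines(paste0("@SQ\tSN:", index$chrom_names, "\tLN:", index$chrom_sizes),
             con, sep = "\n")
  if (nrow(alignments)) {
    stopifnot("seq" %in% names(alignments))
    seq_out <- ifelse(alignments$strand == "-", revcomp(alignments$seq),
                      alignments$seq)
    rec <- paste(alignments$read_id,
                 ifelse(alignments$strand == "-", 16L, 0L),
                 alignments$chrom, alignments$start + 1L, 255L,
                 paste0(nchar(alignments$seq), "M"), "*", 0L, 0L,
                 seq_out, "*",
                 paste0("NM:i:", alignments$n_mismatch),
                 paste0("NH:i:", alignments$n_valid),
                 sep = "\t")
    writeLines(rec, con, sep = "\n")
  }
  invisible(path)
}
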