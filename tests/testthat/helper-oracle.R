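# Independent alignment oracle: full scan of every position and strand via
# Biostrings::matchPattern, with mismatch counts recomputed by direct string
# comparison. Kept free of the package's index/seed machinery.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_align <- function(genome, read, policy) {
  n <- nchar(read)
  budget <- if (policy$mode == "kdiff") policy$v else policy$max_total_mismatches
  out <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else oracle_revcomp(read)
      hits <- Biostrings::matchPattern(q, Biostrings::DNAString(genome[[chrom]]),
                                       max.mismatch = budget)
      st <- BiocGenerics::start(hits)
      en <- BiocGenerics::end(hits)
      full <- en - st + 1L == n & st >= 1L & en <= nchar(genome[[chrom]])
      st <- st[full]; en <- en[full]
      if (!length(st)) next
      qv <- strsplit(q, "")[[1]]
      mm <- vapply(seq_along(st), function(j) {
        sum(strsplit(substr(genome[[chrom]], st[j], en[j]), "")[[1]] != qv)
      }, integer(1))
      keep <- mm <= budget
      if (policy$mode == "maq_like") {
        if (n < policy$seed_len) {
          keep <- rep(FALSE, length(st))
        } else {
          k <- policy$seed_len
          # the read's first k bases sit at the placement's left end on "+"
          # (query is the read) and at its right end on "-" (query is the rc)
          seed_mm <- vapply(seq_along(st), function(j) {
            if (strand == "+") {
              sum(strsplit(substr(genome[[chrom]], st[j], st[j] + k - 1L), "")[[1]] !=
                    qv[1:k])
            } else {
              sum(strsplit(substr(genome[[chrom]], en[j] - k + 1L, en[j]), "")[[1]] !=
                    qv[(n - k + 1L):n])
            }
          }, integer(1))
          keep <- keep & seed_mm <= policy$seed_mismatches
        }
      }
      if (any(keep)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chrom, start = st[keep] - 1L, strand = strand,
          n_mismatch = mm[keep])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          strand = character(), n_mismatch = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, strand)
}

# Exhaustive adapter-trim oracle: try every start position, leftmost match
# wins; mirrors the documented contract, not the implementation.
oracle_trim <- function(read, params) {
  rlen <- nchar(read)
  alen <- nchar(params$adapter)
  for (s in seq_len(rlen)) {
    ov <- min(alen, rlen - s + 1L)
    if (ov < params$min_overlap) break
    rseg <- strsplit(substr(read, s, s + ov - 1L), "")[[1]]
    aseg <- strsplit(substr(params$adapter, 1L, ov), "")[[1]]
    if (sum(rseg != aseg) <= floor(params$max_adapter_mismatch_rate * ov)) {
      return(substr(read, 1L, s - 1L))
    }
  }
  read
}

random_read <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
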