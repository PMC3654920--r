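#' Default tRNA family table for the synthetic reference
#'
#' Five isoacceptor families with the genomic copy numbers reported for the
#' serum tRNA-half study's four dominant isotypes (Gly 29, Val 23, Glu 21,
#' His 11), plus a Cys family standing in for the long tail of rarely
#' observed isotypes. The default geometry (72 nt mature tRNA, anticodon
#' starting at mature position 34) makes cleavage 1-4 nt upstream of the
#' anticodon produce 30-33 nt 5' halves.
#'
#' @return A tibble with columns `isotype`, `anticodon`, `copy_number`,
#'   `trna_length`, `anticodon_pos`.
#' @export
default_trna_families <- function() {
  tibble(
    isotype = c("Gly", "Val", "Glu", "His", "Cys"),
    anticodon = c("GCC", "AAC", "CTC", "GTG", "GCA"),
    copy_number = c(29L, 23L, 21L, 11L, 19L),
    trna_length = 72L,
    anticodon_pos = 34L
  )
}

#' Specification of a synthetic reference genome
#'
#' Parameterizes [build_synthetic_reference()]: which multi-copy tRNA
#' families to scatter over the genome, how many single-copy miRNA, rRNA,
#' other-small-RNA and repeat annotation regions to place, and the
#' chromosome sizes and background base composition.
#'
#' @param families Tibble as returned by [default_trna_families()].
#' @param n_mirna Number of distinct single-copy miRNA loci.
#' @param n_rrna,n_other Number of rRNA and other-small-RNA (scRNA, snRNA,
#'   srpRNA) loci.
#' @param n_repeat_regions Number of repeat annotation intervals (no special
#'   sequence is inserted; the class is consumed by annotation only).
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param flank_composition Probabilities over A, C, G, T for background
#'   sequence.
#' @param mirna_len Length of each miRNA locus (reads are 5' prefixes of it).
#' @param family_divergence Maximum number of substitutions introduced into
#'   each extra copy of a family (default 0: copies are exactly identical,
#'   which is what turns tRNA-half reads into multireads).
#' @param seed Integer seed; builds are byte-identical given the same seed.
#' @return An object of class `reference_spec` (a list of the above).
#' @export
reference_spec <- function(families = default_trna_families(),
                           n_mirna = 12L, n_rrna = 2L, n_other = 3L,
                           n_repeat_regions = 4L,
                           chrom_sizes = c(chr1 = 60000L, chr2 = 60000L, chr3 = 60000L),
                           flank_composition = rep(0.25, 4),
                           mirna_len = 24L,
                           family_divergence = 0L,
                           seed = 1L) {
  stopifnot(is.data.frame(families), nrow(families) >= 1,
            all(families$copy_number >= 1),
            all(families$anticodon_pos >= 1),
            all(families$anticodon_pos <= families$trna_length - 2L),
            all(nchar(families$anticodon) == 3L),
            length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)))
  structure(list(families = as_tibble(families), n_mirna = as.integer(n_mirna),
                 n_rrna = as.integer(n_rrna), n_other = as.integer(n_other),
                 n_repeat_regions = as.integer(n_repeat_regions),
                 chrom_sizes = chrom_sizes,
                 flank_composition = flank_composition,
                 mirna_len = as.integer(mirna_len),
                 family_divergence = as.integer(family_divergence),
                 seed = as.integer(seed)),
            class = "reference_spec")
}

# Place `len`-long intervals without overlap. `occupied` is a per-chrom list
# of two-column matrices (start0, end0, half-open). Returns list(chrom, start0)
# or raises a capacity error.
place_interval <- function(len, chrom_sizes, occupied, max_tries = 2000L) {
  probs <- chrom_sizes / sum(chrom_sizes)
  for (i in seq_len(max_tries)) {
    chrom <- sample(names(chrom_sizes), 1L, prob = probs)
    max_start <- chrom_sizes[[chrom]] - len
    if (max_start < 0) next
    s <- sample.int(max_start + 1L, 1L) - 1L
    occ <- occupied[[chrom]]
    if (is.null(occ) || !any(s < occ[, 2] & (s + len) > occ[, 1])) {
      return(list(chrom = chrom, start = s))
    }
  }
  abort(paste0("cannot place a ", len,
               " bp feature: chromosomes too small or too crowded (capacity error)"),
        class = "trnahalves_capacity_error")
}

#' Build a synthetic genome with multi-copy tRNA families
#'
#' Generates random chromosome sequences and scatters, non-overlapping and on
#' random strands: `copy_number` identical-sequence loci per tRNA family
#' (identical copies are what make 30-33 nt tRNA-half reads multireads),
#' single-copy miRNA loci, rRNA and other small-RNA loci, and repeat
#' annotation intervals. Deterministic given `spec$seed`.
#'
#' @param spec A [reference_spec()].
#' @return An object of class `trna_reference`: a list with `genome` (named
#'   character vector of chromosome sequences) and `features` (tibble with
#'   columns `id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `class`, `isotype`, `anticodon`, `anticodon_pos`, `family_id`,
#'   `sequence` — `sequence` is the mature, strand-corrected sequence).
#' @export
build_synthetic_reference <- function(spec) {
  stopifnot(inherits(spec, "reference_spec"))
  set.seed(spec$seed)
  chrom_sizes <- spec$chrom_sizes
  chroms <- lapply(chrom_sizes, function(n) {
    DNA_BASES[sample.int(4L, n, replace = TRUE, prob = spec$flank_composition)]
  })
  occupied <- setNames(vector("list", length(chrom_sizes)), names(chrom_sizes))

  feats <- list()
  add_feature <- function(id, class, seq_or_len, strand = NULL, insert = TRUE,
                          isotype = NA_character_, anticodon = NA_character_,
                          anticodon_pos = NA_integer_, family_id = NA_character_) {
    len <- if (is.character(seq_or_len)) nchar(seq_or_len) else seq_or_len
    if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
    pos <- place_interval(len, chrom_sizes, occupied)
    occupied[[pos$chrom]] <<- rbind(occupied[[pos$chrom]],
                                    c(pos$start, pos$start + len))
    seq <- NA_character_
    if (is.character(seq_or_len)) {
      seq <- seq_or_len
      genomic <- if (strand == "-") revcomp(seq) else seq
      if (insert) {
        chroms[[pos$chrom]][(pos$start + 1):(pos$start + len)] <<-
          strsplit(genomic, "")[[1]]
      }
    }
    feats[[length(feats) + 1L]] <<- tibble(
      id = id, chrom = pos$chrom, start = pos$start, end = pos$start + len,
      strand = strand, class = class, isotype = isotype, anticodon = anticodon,
      anticodon_pos = anticodon_pos, family_id = family_id, sequence = seq)
    invisible(NULL)
  }

  fam <- spec$families
  for (f in seq_len(nrow(fam))) {
    family_id <- paste0(fam$isotype[f], "-", fam$anticodon[f])
    base_seq <- random_dna(fam$trna_length[f], spec$flank_composition)
    substr(base_seq, fam$anticodon_pos[f], fam$anticodon_pos[f] + 2L) <-
      fam$anticodon[f]
    for (k in seq_len(fam$copy_number[f])) {
      seq <- base_seq
      if (spec$family_divergence > 0L && k > 1L) {
        nsub <- sample.int(spec$family_divergence + 1L, 1L) - 1L
        if (nsub > 0L) {
          # never mutate the anticodon triplet
          ok <- setdiff(seq_len(nchar(seq)),
                        fam$anticodon_pos[f] + 0:2)
          at <- sample(ok, nsub)
          for (p in at) {
            substr(seq, p, p) <- sample(setdiff(DNA_BASES, substr(seq, p, p)), 1L)
          }
        }
      }
      add_feature(id = paste0("tRNA-", family_id, "-", k), class = "tRNA",
                  seq_or_len = seq,
                  isotype = fam$isotype[f], anticodon = fam$anticodon[f],
                  anticodon_pos = fam$anticodon_pos[f], family_id = family_id)
    }
  }
  for (k in seq_len(spec$n_mirna)) {
    add_feature(paste0("mir-", k), "miRNA", random_dna(spec$mirna_len))
  }
  for (k in seq_len(spec$n_rrna)) {
    add_feature(paste0("rRNA-", k), "rRNA", random_dna(120L))
  }
  other_classes <- c("scRNA", "snRNA", "srpRNA")
  for (k in seq_len(spec$n_other)) {
    add_feature(paste0("smRNA-", k), other_classes[1L + (k - 1L) %% 3L],
                random_dna(100L))
  }
  for (k in seq_len(spec$n_repeat_regions)) {
    add_feature(paste0("rep-", k), "repeat", 200L, strand = "+", insert = FALSE)
  }

  genome <- vapply(chroms, paste, character(1), collapse = "")
  features <- bind_rows(feats) %>%
    mutate(sequence = dplyr::if_else(
      is.na(.data$sequence),
      extract_feature_seq(genome, .data$chrom, .data$start, .data$end, .data$strand),
      .data$sequence)) %>%
    arrange(.data$chrom, .data$start)
  new_trna_reference(genome, features)
}

extract_feature_seq <- function(genome, chrom, start, end, strand) {
  s <- substring(genome[chrom], start + 1L, end)
  ifelse(strand == "-", revcomp(s), s)
}

new_trna_reference <- function(genome, features) {
  structure(list(genome = genome, features = as_tibble(features)),
            class = "trna_reference")
}

#' @export
print.trna_reference <- function(x, ...) {
  cat("<trna_reference> ", length(x$genome), " chromosomes (",
      sum(nchar(x$genome)), " bp), ", nrow(x$features), " features\n", sep = "")
  print(count(x$features, .data$class))
  invisible(x)
}

#' Write a reference to FASTA + BED
#'
#' The annotation is BED6 plus five extra tab-separated columns: feature
#' class, isotype, anticodon, 1-based anticodon start within the mature
#' tRNA, and family id (`.` for non-tRNA features). LF line endings, no
#' trailing whitespace; mature sequences are not stored — they are
#' reconstructed from the genome on load.
#'
#' @param ref A `trna_reference`.
#' @param fasta_path,bed_path Output paths.
#' @return `ref`, invisibly.
#' @export
write_reference <- function(ref, fasta_path, bed_path) {
  stopifnot(inherits(ref, "trna_reference"))
  dna <- Biostrings::DNAStringSet(ref$genome)
  Biostrings::writeXStringSet(dna, fasta_path)
  f <- ref$features
  bed <- data.frame(chrom = f$chrom, start = f$start, end = f$end,
                    name = f$id, score = 0L, strand = f$strand,
                    class = f$class,
                    isotype = ifelse(is.na(f$isotype), ".", f$isotype),
                    anticodon = ifelse(is.na(f$anticodon), ".", f$anticodon),
                    anticodon_pos = ifelse(is.na(f$anticodon_pos), ".",
                                           as.character(f$anticodon_pos)),
                    family_id = ifelse(is.na(f$family_id), ".", f$family_id))
  con <- file(bed_path, open = "wb")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(ref)
}

#' Load a reference from FASTA + BED
#'
#' Validates that every feature lies inside its chromosome, that classes come
#' from the fixed vocabulary, and that each tRNA's anticodon triplet sits at
#' its recorded mature position; mature sequences are extracted from the
#' genome (reverse-complemented for minus-strand features).
#'
#' @param fasta_path,bed_path Paths written by [write_reference()].
#' @return A `trna_reference`.
#' @export
load_reference <- function(fasta_path, bed_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  genome <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  lines <- readLines(bed_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 11L)
  if (length(bad)) {
    abort(paste0("malformed annotation record at line ", bad[1],
                 ": expected 11 tab-separated fields, got ",
                 lengths(parts)[bad[1]]),
          class = "trnahalves_parse_error")
  }
  m <- do.call(rbind, parts)
  features <- tibble(
    id = m[, 4], chrom = m[, 1],
    start = suppressWarnings(as.integer(m[, 2])),
    end = suppressWarnings(as.integer(m[, 3])),
    strand = m[, 6], class = m[, 7],
    isotype = dplyr::na_if(m[, 8], "."),
    anticodon = dplyr::na_if(m[, 9], "."),
    anticodon_pos = suppressWarnings(as.integer(dplyr::na_if(m[, 10], "."))),
    family_id = dplyr::na_if(m[, 11], "."))
  if (anyNA(features$start) || anyNA(features$end)) {
    abort(paste0("malformed annotation record at line ",
                 which(is.na(features$start) | is.na(features$end))[1],
                 ": non-integer coordinates"),
          class = "trnahalves_parse_error")
  }
  validate_features(features, genome)
  features$sequence <- extract_feature_seq(genome, features$chrom,
                                           features$start, features$end,
                                           features$strand)
  trna <- features$class == "tRNA"
  ac <- substr(features$sequence[trna], features$anticodon_pos[trna],
               features$anticodon_pos[trna] + 2L)
  if (any(ac != features$anticodon[trna])) {
    abort("tRNA feature whose sequence does not carry its anticodon at anticodon_pos",
          class = "trnahalves_validation_error")
  }
  new_trna_reference(genome, features)
}

validate_features <- function(features, genome) {
  if (!all(features$chrom %in% names(genome))) {
    abort("feature on unknown chromosome", class = "trnahalves_validation_error")
  }
  sizes <- nchar(genome)[features$chrom]
  if (any(features$start < 0 | features$end > sizes | features$start >= features$end)) {
    abort("feature interval outside its chromosome",
          class = "trnahalves_validation_error")
  }
  if (!all(features$class %in% FEATURE_CLASSES)) {
    abort(paste0("unknown feature class: ",
                 paste(setdiff(features$class, FEATURE_CLASSES), collapse = ", ")),
          class = "trnahalves_validation_error")
  }
  trna <- features$class == "tRNA"
  len <- features$end[trna] - features$start[trna]
  ap <- features$anticodon_pos[trna]
  if (anyNA(ap) || any(ap < 1L | ap > len - 2L)) {
    abort("tRNA anticodon_pos outside 1..length-2",
          class = "trnahalves_validation_error")
  }
  invisible(features)
}

#' Map a genomic position into mature-tRNA coordinates
#'
#' Position 1 is the mature 5' nucleotide regardless of strand; for a
#' minus-strand gene the last genomic base of the interval is position 1.
#'
#' @param gene A one-row tibble (or list) with `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param genomic_pos 0-based genomic position(s) inside the gene.
#' @return 1-based position(s) within the mature tRNA.
#' @export
trna_coordinate <- function(gene, genomic_pos) {
  if (any(genomic_pos < gene$start | genomic_pos >= gene$end)) {
    abort("genomic position outside the gene interval",
          class = "trnahalves_range_error")
  }
  if (gene$strand == "+") genomic_pos - gene$start + 1L
  else gene$end - genomic_pos
}
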