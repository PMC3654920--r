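#' Default feature-class priority
#'
#' When a read overlaps several feature classes it is assigned the
#' highest-priority one. tRNA outranks everything (the tRNA/miRNA annotation
#' is primary and repeat-only reads are dropped from downstream analysis).
#'
#' @return Character vector ordering `tRNA`, `miRNA`, `rRNA`, `other_smRNA`,
#'   `repeat` from highest to lowest priority.
#' @export
class_priority <- function() {
  c("tRNA", "miRNA", "rRNA", "other_smRNA", "repeat")
}

# Track classes -> read-annotation classes.
collapse_class <- function(x) {
  dplyr::case_match(x,
    "tRNA" ~ "tRNA", "miRNA" ~ "miRNA", "rRNA" ~ "rRNA",
    c("scRNA", "snRNA", "srpRNA") ~ "other_smRNA", "repeat" ~ "repeat")
}

# Mature-tRNA coordinate without the range check (can fall outside 1..len for
# read termini that overhang the gene).
mature_pos <- function(gene_start, gene_end, gene_strand, gpos) {
  ifelse(gene_strand == "+", gpos - gene_start + 1L, gene_end - gpos)
}

#' Classify a tRNA-overlapping read by its tRNA end
#'
#' A read is `tRNA_5p` iff its 5' terminus falls within `tol5` nt of mature
#' position 1, `tRNA_3p` iff its 3' terminus falls within `tol3` nt of the
#' mature 3' end, otherwise `tRNA_internal`; `tRNA_5p` wins when both hold
#' (degenerate short genes).
#'
#' @param alignment One-row tibble/list with `chrom`, `start` (0-based),
#'   `strand` and `seq` or `len`.
#' @param gene One-row tibble for the tRNA feature (with `start`, `end`,
#'   `strand`, `sequence`).
#' @param tol5,tol3 Tolerances in nt (default 2).
#' @return One of `"tRNA_5p"`, `"tRNA_3p"`, `"tRNA_internal"`.
#' @export
classify_trna_end <- function(alignment, gene, tol5 = 2L, tol3 = 2L) {
  len <- if ("len" %in% names(alignment)) alignment$len else nchar(alignment$seq)
  a_start <- alignment$start
  a_end <- alignment$start + len
  if (a_end <= gene$start || a_start >= gene$end) {
    abort("alignment does not overlap the gene",
          class = "trnahalves_contract_error")
  }
  cls <- classify_trna_end_vec(a_start, a_end, alignment$strand,
                               gene$start, gene$end, gene$strand,
                               nchar(gene$sequence), tol5, tol3)$class
  cls
}

classify_trna_end_vec <- function(a_start, a_end, a_strand,
                                  g_start, g_end, g_strand, g_len,
                                  tol5, tol3) {
  g5 <- ifelse(a_strand == "+", a_start, a_end - 1L)
  g3 <- ifelse(a_strand == "+", a_end - 1L, a_start)
  m5 <- mature_pos(g_start, g_end, g_strand, g5)
  m3 <- mature_pos(g_start, g_end, g_strand, g3)
  is5 <- abs(m5 - 1L) <= tol5
  is3 <- abs(m3 - g_len) <= tol3
  cls <- ifelse(is5, "tRNA_5p", ifelse(is3, "tRNA_3p", "tRNA_internal"))
  list(class = cls, m5 = m5, m3 = m3)
}

#' Annotate reported alignments against the feature track
#'
#' Each alignment is assigned the highest-priority class among the features
#' it overlaps by at least one base. Genic classes require the feature's
#' strand (configurable); repeats are strandless. tRNA-assigned reads are
#' further split into 5'/3'/internal by [classify_trna_end()] and, for 5'
#' halves, carry `cleavage_pos` — the mature-tRNA position of the read's 3'
#' terminal base.
#'
#' @param alignments Reported alignments with `read_id`, `chrom`, `start`,
#'   `strand` and `seq` (or `len`).
#' @param features The feature tibble of a `trna_reference` (or the
#'   reference itself).
#' @param priority Class priority, as [class_priority()].
#' @param tol5,tol3 End-classification tolerances (nt).
#' @param stranded Require strand match for genic classes (default TRUE).
#' @return Tibble: `read_id`, `feature_class` (one of tRNA_5p, tRNA_3p,
#'   tRNA_internal, miRNA, rRNA, other_smRNA, repeat, none), `locus_id`,
#'   `read_len`, `cleavage_pos`.
#' @export
annotate_alignments <- function(alignments, features,
                                priority = class_priority(),
                                tol5 = 2L, tol3 = 2L, stranded = TRUE) {
  chrom_universe <- NULL
  if (inherits(features, "trna_reference")) {
    chrom_universe <- names(features$genome)
    features <- features$features
  }
  stopifnot(setequal(priority, class_priority()))
  if (!nrow(alignments)) {
    return(tibble(read_id = character(), feature_class = character(),
                  locus_id = character(), read_len = integer(),
                  cleavage_pos = integer()))
  }
  if (!is.null(chrom_universe) && !all(alignments$chrom %in% chrom_universe)) {
    abort(paste0("alignment references unknown chromosome: ",
                 paste(setdiff(alignments$chrom, chrom_universe), collapse = ", ")),
          class = "trnahalves_validation_error")
  }
  len <- if ("len" %in% names(alignments)) alignments$len else nchar(alignments$seq)

  al_gr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(start = alignments$start + 1L, width = len),
    strand = alignments$strand)
  ft_gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  ov <- GenomicRanges::findOverlaps(al_gr, ft_gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  fi <- S4Vectors::subjectHits(ov)
  f_class <- features$class[fi]
  strand_ok <- f_class == "repeat" | !stranded |
    alignments$strand[qi] == features$strand[fi]
  qi <- qi[strand_ok]; fi <- fi[strand_ok]

  cls <- collapse_class(features$class[fi])
  rank <- match(cls, priority)
  hit <- tibble(qi = qi, fi = fi, rank = rank) %>%
    arrange(.data$qi, .data$rank, .data$fi) %>%
    group_by(.data$qi) %>% slice(1L) %>% ungroup()

  out <- tibble(read_id = alignments$read_id,
                feature_class = "none",
                locus_id = NA_character_,
                read_len = as.integer(len),
                cleavage_pos = NA_integer_)
  out$feature_class[hit$qi] <- priority[hit$rank]
  out$locus_id[hit$qi] <- features$id[hit$fi]

  tr <- hit %>% filter(priority[.data$rank] == "tRNA")
  if (nrow(tr)) {
    i <- tr$qi; j <- tr$fi
    cv <- classify_trna_end_vec(
      alignments$start[i], alignments$start[i] + len[i], alignments$strand[i],
      features$start[j], features$end[j], features$strand[j],
      nchar(features$sequence[j]), tol5, tol3)
    out$feature_class[i] <- cv$class
    out$cleavage_pos[i] <- ifelse(cv$class == "tRNA_5p",
                                  as.integer(cv$m3), NA_integer_)
  }
  out
}

#' Read-length histogram by feature class
#'
#' @param annotations Output of [annotate_alignments()].
#' @param lengths Length range of the histogram (default 5-48 nt, the mapped
#'   size range).
#' @param label Optional policy-combination label column.
#' @return Tibble `length` x `feature_class` x `count` over the full grid;
#'   counts sum to `nrow(annotations)` when all read lengths fall in range.
#' @export
length_histogram <- function(annotations, lengths = 5:48, label = NULL) {
  grid <- tidyr::expand_grid(length = as.integer(lengths),
                             feature_class = READ_CLASSES)
  h <- annotations %>%
    count(length = .data$read_len, .data$feature_class, name = "count")
  out <- grid %>%
    left_join(h, by = c("length", "feature_class")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  if (!is.null(label)) out$policy_combo <- label
  out
}

#' Anticodon-relative cleavage-site profile of 5' halves
#'
#' For each family, the fraction of 5'-half reads whose 3' terminus falls at
#' each mature position, reported with the offset upstream of the anticodon
#' (`offset = anticodon_pos - cleavage_pos`; positive offsets are upstream of
#' the anticodon's first base).
#'
#' @param annotations Output of [annotate_alignments()] (only `tRNA_5p` rows
#'   are used).
#' @param features Feature tibble or `trna_reference`.
#' @return Tibble `family_id`, `cleavage_pos`, `offset`, `n_reads`,
#'   `fraction` (fractions sum to 1 within each family).
#' @export
cleavage_profile <- function(annotations, features) {
  if (inherits(features, "trna_reference")) features <- features$features
  lk <- features %>% filter(.data$class == "tRNA") %>%
    select(locus_id = "id", "family_id", "anticodon_pos")
  annotations %>%
    filter(.data$feature_class == "tRNA_5p") %>%
    inner_join(lk, by = "locus_id") %>%
    count(.data$family_id, .data$anticodon_pos, .data$cleavage_pos,
          name = "n_reads") %>%
    group_by(.data$family_id) %>%
    mutate(fraction = .data$n_reads / sum(.data$n_reads)) %>%
    ungroup() %>%
    mutate(offset = .data$anticodon_pos - .data$cleavage_pos) %>%
    select("family_id", "cleavage_pos", "offset", "n_reads", "fraction")
}

#' Isoacceptor frequencies among tRNA-half reads
#'
#' @param annotations Output of [annotate_alignments()]; `tRNA_5p` and
#'   `tRNA_3p` reads are counted.
#' @param features Feature tibble or `trna_reference`.
#' @return Tibble `isotype`, `copy_number` (genomic loci for that isotype),
#'   `n_reads`, `fraction` (fractions sum to 1).
#' @export
isoacceptor_frequencies <- function(annotations, features) {
  if (inherits(features, "trna_reference")) features <- features$features
  trna <- features %>% filter(.data$class == "tRNA")
  copies <- trna %>% count(.data$isotype, name = "copy_number")
  lk <- trna %>% select(locus_id = "id", "isotype")
  annotations %>%
    filter(.data$feature_class %in% c("tRNA_5p", "tRNA_3p")) %>%
    inner_join(lk, by = "locus_id") %>%
    count(.data$isotype, name = "n_reads") %>%
    mutate(fraction = .data$n_reads / sum(.data$n_reads)) %>%
    left_join(copies, by = "isotype") %>%
    select("isotype", "copy_number", "n_reads", "fraction") %>%
    arrange(dplyr::desc(.data$fraction))
}
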