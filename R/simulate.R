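#' Default per-family abundance weights
#'
#' Relative abundances of circulating 5' tRNA halves by isoacceptor family,
#' matching the observed shares (Gly 46%, Val 44%, Glu 8%, His 1%, rest <1%).
#' @return Named numeric vector keyed by `family_id`.
#' @export
default_family_weights <- function() {
  c("Gly-GCC" = 0.46, "Val-AAC" = 0.44, "Glu-CTC" = 0.08,
    "His-GTG" = 0.01, "Cys-GCA" = 0.01)
}

#' Default group effects for the age / calorie-restriction design
#'
#' Multiplicative family-abundance effects for the old-control and old-CR
#' groups relative to young controls, shaped like the reported age and CR
#' fold changes (Gly down ~4.5x with age, unchanged by CR; Val down ~2.8x,
#' partially restored by CR; His up ~3.8x, halved by CR; Cys down ~2.6x,
#' partially restored; Glu unchanged).
#' @return Tibble with columns `family_id`, `old_control`, `old_CR`.
#' @export
default_group_effects <- function() {
  tibble(family_id = c("Gly-GCC", "Val-AAC", "Glu-CTC", "His-GTG", "Cys-GCA"),
         old_control = c(1 / 4.5, 1 / 2.8, 1, 3.8, 1 / 2.6),
         old_CR = c(1 / 4.5, 1.8 / 2.8, 1, 1.9, 1.8 / 2.6))
}

#' Read-mixture specification for the simulator
#'
#' Defines the generative law of one serum small-RNA library: class mix
#' (5' halves, trace 3' halves, trace full-length tRNAs, miRNAs, genomic
#' background fragments), the cleavage-site distribution over offsets 1-4 nt
#' upstream of the anticodon (defaults tuned so 30/31/32/33 nt halves occur
#' at 23/17/35/26%), miRNA length distribution over 20-24 nt, per-family
#' abundance weights, group effects, NB dispersion of family totals across
#' replicates, sequencing error rate, and the 3' adapter.
#'
#' @param frac_5p_half,frac_3p_half,frac_full_trna,frac_mirna,frac_noise
#'   Class probabilities; must sum to 1.
#' @param cleavage_site_probs Named probabilities over offsets `1:4` (nt
#'   upstream of the anticodon); must sum to 1.
#' @param length_probs_mirna Named probabilities over miRNA read lengths 20-24.
#' @param family_weights Named weights over `family_id`s (>= 0).
#' @param group_effects Tibble as [default_group_effects()].
#' @param dispersion NB dispersion of per-sample family totals (gamma-Poisson).
#' @param seq_error_rate Per-base substitution error probability.
#' @param adapter 3' adapter appended to each insert before truncation.
#' @param read_len Raw read length (nt).
#' @param n_reads Reads per sample.
#' @param frac_low_quality Fraction of reads emitted with degraded (Q2)
#'   quality strings, to exercise the quality filter.
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(frac_5p_half = 0.55, frac_3p_half = 0.004,
                         frac_full_trna = 0.006, frac_mirna = 0.30,
                         frac_noise = 0.14,
                         cleavage_site_probs = c("1" = 18724475, "2" = 25190160,
                                                 "3" = 12343893, "4" = 16649224) /
                           72907752,
                         length_probs_mirna = c("20" = 0.15, "21" = 0.20,
                                                "22" = 0.30, "23" = 0.20,
                                                "24" = 0.15),
                         family_weights = default_family_weights(),
                         group_effects = default_group_effects(),
                         dispersion = 0.1,
                         seq_error_rate = 0.001,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         read_len = 50L, n_reads = 10000L,
                         frac_low_quality = 0) {
  fr <- c(frac_5p_half, frac_3p_half, frac_full_trna, frac_mirna, frac_noise)
  if (abs(sum(fr) - 1) > 1e-8) {
    abort("class fractions must sum to 1", class = "trnahalves_validation_error")
  }
  if (abs(sum(cleavage_site_probs) - 1) > 1e-8) {
    abort("cleavage_site_probs must sum to 1",
          class = "trnahalves_validation_error")
  }
  stopifnot(all(family_weights >= 0), dispersion >= 0,
            seq_error_rate >= 0, seq_error_rate < 1)
  structure(list(frac_5p_half = frac_5p_half, frac_3p_half = frac_3p_half,
                 frac_full_trna = frac_full_trna, frac_mirna = frac_mirna,
                 frac_noise = frac_noise,
                 cleavage_site_probs = cleavage_site_probs,
                 length_probs_mirna = length_probs_mirna,
                 family_weights = family_weights,
                 group_effects = as_tibble(group_effects),
                 dispersion = dispersion, seq_error_rate = seq_error_rate,
                 adapter = adapter, read_len = as.integer(read_len),
                 n_reads = as.integer(n_reads),
                 frac_low_quality = frac_low_quality),
            class = "mixture_spec")
}

mutate_bases <- function(seqs, rate) {
  if (rate <= 0) return(list(seqs = seqs, n_errors = integer(length(seqs))))
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    at <- sample.int(lens[i], nerr[i])
    for (p in at) {
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, substr(seqs[i], p, p)), 1L)
    }
  }
  list(seqs = seqs, n_errors = nerr)
}

#' Simulate one small-RNA sequencing sample
#'
#' Each read draws a class from the mixture; 5' halves are exact prefixes of
#' a mature tRNA ending `offset` nt upstream of the anticodon (offset from
#' `cleavage_site_probs`), with the genomic locus chosen uniformly among the
#' family's copies; 3' halves are the complementary suffixes; miRNA reads are
#' 20-24 nt prefixes of a single-copy miRNA locus; background reads are
#' random genomic fragments of 5-48 nt from either strand. The 3' adapter is
#' appended and the read truncated to `read_len`; substitution errors are
#' applied at `seq_error_rate`. Deterministic given `seed`.
#'
#' @param ref A `trna_reference`.
#' @param mix A [mixture_spec()].
#' @param seed Integer seed.
#' @param sample_id Prefix for read ids.
#' @return List with `reads` (tibble `read_id`, `seq`, `qual`) and `truth`
#'   (tibble `read_id`, `origin_class`, `family_id`, `locus_id`,
#'   `cleavage_pos` (mature 1-based 3' end of 5' halves / cleavage site of 3'
#'   halves), `intended_length`, `n_errors`).
#' @export
simulate_sample <- function(ref, mix, seed = 1L, sample_id = "s1") {
  stopifnot(inherits(ref, "trna_reference"), inherits(mix, "mixture_spec"))
  set.seed(seed)
  n <- mix$n_reads
  empty <- list(
    reads = tibble(read_id = character(), seq = character(), qual = character()),
    truth = tibble(read_id = character(), origin_class = character(),
                   family_id = character(), locus_id = character(),
                   cleavage_pos = integer(), intended_length = integer(),
                   n_errors = integer()))
  if (n == 0L) return(empty)

  trna <- filter(ref$features, .data$class == "tRNA")
  mirna <- filter(ref$features, .data$class == "miRNA")
  fams <- unique(trna$family_id)
  w <- mix$family_weights[names(mix$family_weights) %in% fams]
  if (!length(w)) {
    abort("no family_weights match the reference families",
          class = "trnahalves_validation_error")
  }

  classes <- sample(c("tRNA_5p", "tRNA_3p", "full_tRNA", "miRNA", "noise"), n,
                    replace = TRUE,
                    prob = c(mix$frac_5p_half, mix$frac_3p_half,
                             mix$frac_full_trna, mix$frac_mirna, mix$frac_noise))
  read_id <- sprintf("%s_r%06d", sample_id, seq_len(n))
  insert <- character(n)
  family_id <- rep(NA_character_, n)
  locus_id <- rep(NA_character_, n)
  cleavage_pos <- rep(NA_integer_, n)

  is_half <- classes %in% c("tRNA_5p", "tRNA_3p", "full_tRNA")
  nh <- sum(is_half)
  if (nh) {
    hi <- which(is_half)
    fam_pick <- sample(names(w), nh, replace = TRUE, prob = w)
    offs <- as.integer(sample(names(mix$cleavage_site_probs), nh,
                              replace = TRUE, prob = mix$cleavage_site_probs))
    fam_split <- split(seq_len(nrow(trna)), trna$family_id)
    pick <- vapply(fam_pick, function(f) {
      ix <- fam_split[[f]]
      ix[sample.int(length(ix), 1L)]
    }, integer(1), USE.NAMES = FALSE)
    gseq <- trna$sequence[pick]
    apos <- trna$anticodon_pos[pick]
    family_id[hi] <- fam_pick
    locus_id[hi] <- trna$id[pick]
    cls <- classes[hi]
    cp <- apos - offs
    cleavage_pos[hi] <- ifelse(cls == "full_tRNA", NA_integer_, cp)
    insert[hi] <- ifelse(cls == "tRNA_5p", substr(gseq, 1L, cp),
                  ifelse(cls == "tRNA_3p", substr(gseq, cp + 1L, nchar(gseq)),
                         gseq))
  }
  im <- which(classes == "miRNA")
  if (length(im)) {
    if (!nrow(mirna)) {
      abort("mixture requests miRNA reads but the reference has no miRNA loci",
            class = "trnahalves_validation_error")
    }
    mi <- sample.int(nrow(mirna), length(im), replace = TRUE)
    ml <- as.integer(sample(names(mix$length_probs_mirna), length(im),
                            replace = TRUE, prob = mix$length_probs_mirna))
    ml <- pmin(ml, nchar(mirna$sequence[mi]))
    insert[im] <- substr(mirna$sequence[mi], 1L, ml)
    locus_id[im] <- mirna$id[mi]
  }
  ino <- which(classes == "noise")
  if (length(ino)) {
    sizes <- nchar(ref$genome)
    ch <- sample(names(ref$genome), length(ino), replace = TRUE,
                 prob = sizes / sum(sizes))
    ln <- sample(5:48, length(ino), replace = TRUE)
    st <- vapply(seq_along(ino), function(j) {
      sample.int(sizes[[ch[j]]] - ln[j] + 1L, 1L)
    }, integer(1))
    frag <- substring(ref$genome[ch], st, st + ln - 1L)
    neg <- runif(length(ino)) < 0.5
    if (any(neg)) frag[neg] <- revcomp(frag[neg])
    insert[ino] <- frag
  }

  raw <- substr(paste0(insert, mix$adapter, strrep("A", mix$read_len)),
                1L, mix$read_len)
  mut <- mutate_bases(raw, mix$seq_error_rate)
  qual <- rep(strrep("I", mix$read_len), n)
  if (mix$frac_low_quality > 0) {
    lowq <- runif(n) < mix$frac_low_quality
    qual[lowq] <- strrep("#", mix$read_len)
  }
  list(reads = tibble(read_id = read_id, seq = mut$seqs, qual = qual),
       truth = tibble(read_id = read_id, origin_class = classes,
                      family_id = family_id, locus_id = locus_id,
                      cleavage_pos = cleavage_pos,
                      intended_length = nchar(insert),
                      n_errors = mut$n_errors))
}

#' Simulate a multi-sample experiment with group effects
#'
#' For each sample, the family abundance weights are multiplied by the
#' group's effects (young controls are the reference) and by a per-sample
#' gamma multiplier with shape/rate `1/dispersion`, then exactly `n_reads`
#' reads are drawn; family totals are thus marginally negative-binomial with
#' the requested dispersion while per-sample read totals stay exact.
#'
#' @param ref A `trna_reference`.
#' @param base_mix A [mixture_spec()].
#' @param design Tibble with columns `sample` and `group`; groups must be
#'   `young_control`, `old_control` or `old_CR`.
#' @param seeds Integer seeds, one per sample.
#' @return List with `samples` (named list of [simulate_sample()] results)
#'   and `design`.
#' @export
simulate_experiment <- function(ref, base_mix, design = default_design(),
                                seeds = seq_len(nrow(design))) {
  groups <- c("young_control", "old_control", "old_CR")
  if (!all(design$group %in% groups)) {
    abort(paste0("unknown group label: ",
                 paste(setdiff(design$group, groups), collapse = ", ")),
          class = "trnahalves_validation_error")
  }
  stopifnot(length(seeds) == nrow(design))
  eff <- base_mix$group_effects
  samples <- vector("list", nrow(design))
  names(samples) <- design$sample
  for (i in seq_len(nrow(design))) {
    set.seed(seeds[i])
    w <- base_mix$family_weights
    if (design$group[i] != "young_control") {
      e <- eff[[design$group[i]]][match(names(w), eff$family_id)]
      e[is.na(e)] <- 1
      w <- w * e
    }
    if (base_mix$dispersion > 0) {
      w <- w * rgamma(length(w), shape = 1 / base_mix$dispersion,
                      rate = 1 / base_mix$dispersion)
    }
    mix_i <- base_mix
    mix_i$family_weights <- w
    # the tRNA-half compartment grows/shrinks with its families' total mass,
    # so a family's effect moves its absolute count, not just its share;
    # read totals stay fixed (constant sequencing depth), so strong global
    # shifts still compress counts compositionally, as in real libraries
    s <- sum(w) / sum(base_mix$family_weights)
    m <- c(base_mix$frac_5p_half * s, base_mix$frac_3p_half * s,
           base_mix$frac_full_trna, base_mix$frac_mirna, base_mix$frac_noise)
    m <- m / sum(m)
    mix_i$frac_5p_half <- m[1]; mix_i$frac_3p_half <- m[2]
    mix_i$frac_full_trna <- m[3]; mix_i$frac_mirna <- m[4]
    mix_i$frac_noise <- m[5]
    sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    samples[[i]] <- simulate_sample(ref, mix_i, seed = sub_seed,
                                    sample_id = design$sample[i])
  }
  list(samples = samples, design = as_tibble(design))
}

#' The study's 3x3 design: three mice per group
#' @return Tibble with columns `sample`, `group`.
#' @export
default_design <- function() {
  tibble(sample = paste0(rep(c("young", "old", "oldCR"), each = 3), 1:3),
         group = rep(c("young_control", "old_control", "old_CR"), each = 3))
}

#' Write reads to FASTQ (Phred+33)
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into a tidy read table
#' @param path FASTQ path.
#' @return Tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = sub("\\s.*$", "", names(dna)),
         seq = unname(as.character(dna)),
         qual = unname(as.character(S4Vectors::mcols(dna)$qualities)))
}
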