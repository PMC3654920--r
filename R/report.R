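#' Mapping summary with the published rounding conventions
#'
#' Derived percentages recompute exactly from the count fields: overall
#' mapped percentage to one decimal; the small-RNA share of mapped reads and
#' the per-class shares of small-RNA-mapped reads as integer percents.
#'
#' @param n_preprocessed,n_mapped Read counts (mapped <= preprocessed).
#' @param class_counts Named counts over
#'   `tRNA, miRNA, rRNA, other_smRNA, repeat, none`; missing classes count 0.
#'   Must sum to `n_mapped`.
#' @return One-row tibble with the counts, `n_small_rna`, `pct_mapped` (1
#'   decimal), `pct_small_rna`, `pct_trna`, `pct_mirna` (integer percents of
#'   their stated denominators).
#' @export
summarize_mapping <- function(n_preprocessed, n_mapped, class_counts) {
  if (n_mapped > n_preprocessed) {
    abort("more mapped than preprocessed reads",
          class = "trnahalves_validation_error")
  }
  all_classes <- c("tRNA", "miRNA", "rRNA", "other_smRNA", "repeat", "none")
  if (!all(names(class_counts) %in% all_classes)) {
    abort(paste0("unknown class in class_counts: ",
                 paste(setdiff(names(class_counts), all_classes), collapse = ", ")),
          class = "trnahalves_validation_error")
  }
  cc <- setNames(rep(0, length(all_classes)), all_classes)
  cc[names(class_counts)] <- class_counts
  if (abs(sum(cc) - n_mapped) > 0.5) {
    abort("class counts must sum to the number of mapped reads",
          class = "trnahalves_validation_error")
  }
  n_small <- sum(cc[c("tRNA", "miRNA", "rRNA", "other_smRNA")])
  tibble(n_preprocessed = n_preprocessed, n_mapped = n_mapped,
         n_small_rna = n_small,
         n_trna = cc[["tRNA"]], n_mirna = cc[["miRNA"]],
         n_repeat = cc[["repeat"]],
         pct_mapped = round(n_mapped / n_preprocessed * 100, 1),
         pct_small_rna = round(n_small / n_mapped * 100),
         pct_trna = round(cc[["tRNA"]] / n_small * 100),
         pct_mirna = round(cc[["miRNA"]] / n_small * 100),
         pct_repeat = round(cc[["repeat"]] / n_mapped * 100))
}

#' Size shares of tRNA-mapped reads
#'
#' @param counts_by_length Named read counts (names = lengths, typically
#'   30-33).
#' @return Tibble `length`, `count`, `percent` (integer percent of the
#'   total, so rows can sum to slightly more or less than 100).
#' @export
size_share_table <- function(counts_by_length) {
  if (any(counts_by_length < 0) || sum(counts_by_length) == 0) {
    abort("counts must be nonnegative and not all zero",
          class = "trnahalves_validation_error")
  }
  tibble(length = as.integer(names(counts_by_length)),
         count = unname(as.numeric(counts_by_length)),
         percent = unname(round(counts_by_length / sum(counts_by_length) * 100)))
}

study_extdata <- function(file) {
  path <- system.file("extdata", file, package = "trnahalves")
  if (path == "") path <- file.path("inst", "extdata", file)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE) %>% as_tibble()
}

#' Published summary tables bundled with the package
#'
#' Plain-text copies of the original serum small-RNA study's printed
#' numbers, used as inputs to the report operations: overall mapping and
#' annotation counts, tRNA read-size counts, and the per-locus group mean
#' counts with published fold changes and p-values.
#'
#' @return Named list of tibbles: `mapping` (one row per count, with a
#'   `provenance` column marking printed vs derived-from-printed-percent
#'   values), `sizes`, `diff`.
#' @export
study_tables <- function() {
  list(mapping = study_extdata("study_mapping_counts.tsv"),
       sizes = study_extdata("study_trna_size_counts.tsv"),
       diff = study_extdata("study_diff_group_means.tsv"))
}

#' Run the full pipeline on simulated data
#'
#' Orchestrates: synthetic reference -> simulated experiment -> adapter/
#' quality preprocessing -> alignment under the 2x2 policy grid (two
#' alignment policies x two reporting policies) -> annotation and end
#' classification (on the maq-like / best-one combination) -> per-locus
#' counting, TMM normalization, CPM filtering, dispersion estimation and NB
#' GLM LRT contrasts -> tidy TSV reports plus a JSON manifest with MD5
#' checksums. Fully deterministic given `seed`.
#'
#' @param out_dir Output directory (created).
#' @param ref_spec A [reference_spec()].
#' @param mix A [mixture_spec()].
#' @param design Sample/group design tibble.
#' @param pre A [preprocess_params()] (defaults to the mixture's adapter).
#' @param min_cpm CPM filter threshold.
#' @param seed Global seed; per-sample seeds derive from it.
#' @return The manifest, invisibly (list with file table and settings).
#' @export
run_pipeline <- function(out_dir, ref_spec = reference_spec(),
                         mix = mixture_spec(), design = default_design(),
                         pre = preprocess_params(adapter = mix$adapter),
                         min_cpm = 500, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- build_synthetic_reference(ref_spec)
  write_reference(ref, file.path(out_dir, "reference.fa"),
                  file.path(out_dir, "features.bed"))
  sim <- simulate_experiment(ref, mix, design,
                             seeds = seed + seq_len(nrow(design)))
  index <- build_index(ref)
  policies <- list(maq_like = align_policy("maq_like"),
                   kdiff = align_policy("kdiff"))
  modes <- c("best_one", "unique_only")

  histos <- list()
  annotations <- list()
  pre_logs <- list()
  n_mapped <- integer(0)
  for (s in names(sim$samples)) {
    pp <- preprocess_reads(sim$samples[[s]]$reads, pre)
    write_fastq(pp$reads, file.path(out_dir, paste0(s, ".fastq")))
    pre_logs[[s]] <- mutate(pp$log, sample = s, .before = 1)
    for (pol in names(policies)) {
      al <- align_reads(pp$reads, index, policies[[pol]])
      for (m in modes) {
        rep_al <- report_alignments(al, m) %>%
          inner_join(select(pp$reads, "read_id", "seq"), by = "read_id")
        ann <- annotate_alignments(rep_al, ref)
        combo <- paste(pol, m, sep = "/")
        histos[[paste(s, combo)]] <-
          length_histogram(ann, label = combo) %>%
          mutate(sample = s, .before = 1)
        if (pol == "maq_like" && m == "best_one") {
          annotations[[s]] <- mutate(ann, sample = s, .before = 1)
          n_mapped[s] <- nrow(rep_al)
          write_sam(rep_al, index, file.path(out_dir, paste0(s, ".sam")))
        }
      }
    }
  }
  ann_all <- bind_rows(annotations)
  hist_all <- bind_rows(histos)
  pre_all <- bind_rows(pre_logs)

  class_counts <- ann_all %>%
    mutate(cls = dplyr::case_match(.data$feature_class,
      c("tRNA_5p", "tRNA_3p", "tRNA_internal") ~ "tRNA",
      .default = .data$feature_class)) %>%
    count(.data$cls) %>% { setNames(.$n, .$cls) }
  mapping <- summarize_mapping(sum(pre_all$n_out), sum(n_mapped), class_counts)

  cleav <- cleavage_profile(ann_all, ref)
  iso <- isoacceptor_frequencies(ann_all, ref)
  sizes <- ann_all %>%
    filter(.data$feature_class %in% c("tRNA_5p", "tRNA_3p", "tRNA_internal"),
           .data$read_len %in% 30:33) %>%
    count(.data$read_len) %>% { setNames(.$n, .$read_len) }
  size_tab <- if (length(sizes)) size_share_table(sizes) else
    tibble(length = integer(), count = numeric(), percent = numeric())

  cm <- count_loci(ann_all, design) %>% tmm_normalize() %>%
    filter_low(min_cpm = min_cpm)
  diff_tab <- tibble()
  if (nrow(cm$counts) > 0) {
    fit <- fit_and_test(cm, estimate_dispersion(cm))
    diff_tab <- tidy(fit)
  }

  reports <- list(mapping_summary = mapping, length_histograms = hist_all,
                  preprocess_log = pre_all, trna_size_shares = size_tab,
                  cleavage_profile = cleav, isoacceptor_frequencies = iso,
                  diff_results = diff_tab)
  for (nm in names(reports)) {
    write_tsv_lf(reports[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  counts_out <- as_tibble(cm$counts, rownames = "locus")
  write_tsv_lf(counts_out, file.path(out_dir, "counts.tsv"))

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(seed = seed,
                   n_samples = nrow(design),
                   files = data.frame(path = basename(files),
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_tsv_lf <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
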