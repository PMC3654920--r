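# Shared builders: a small reference whose families keep the multi-copy
# structure but at desk scale, and a mixture sized for fast tests.

tiny_families <- function() {
  tibble::tibble(
    isotype = c("Gly", "Val", "Ala"),
    anticodon = c("GCC", "AAC", "AGC"),
    copy_number = c(5L, 3L, 1L),
    trna_length = 72L,
    anticodon_pos = 34L)
}

tiny_ref <- function(seed = 42L, ...) {
  build_synthetic_reference(reference_spec(
    families = tiny_families(),
    n_mirna = 4L, n_rrna = 1L, n_other = 1L, n_repeat_regions = 2L,
    chrom_sizes = c(chrA = 6000L, chrB = 5000L),
    seed = seed, ...))
}

tiny_weights <- c("Gly-GCC" = 0.6, "Val-AAC" = 0.3, "Ala-AGC" = 0.1)

tiny_mix <- function(n_reads = 2000L, ...) {
  mixture_spec(n_reads = n_reads, family_weights = tiny_weights, ...)
}

# Overlap check used by reference invariants: within each chromosome, sorted
# intervals must not intersect.
has_overlaps <- function(features) {
  any(vapply(split(features, features$chrom), function(f) {
    f <- f[order(f$start), ]
    nrow(f) > 1 && any(f$start[-1] < head(f$end, -1))
  }, logical(1)))
}
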