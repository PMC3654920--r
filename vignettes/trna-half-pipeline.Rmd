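---
title: "Detecting circulating 5' tRNA halves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circulating 5' tRNA halves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serum small RNA-seq libraries contain, beside the familiar 20–24 nt miRNA
peak, a second population of 30–33 nt reads that derive from the 5' ends of
mature tRNAs cleaved in the anticodon loop ("5' tRNA halves" or tiRNAs).
These reads are invisible to naive alignment pipelines for a structural
reason: tRNA genes occur in families of many identical genomic copies, so a
tRNA-half read has dozens of equally good alignments. A reporting policy
that suppresses multireads (bowtie's `-m 1` behaviour) silently removes the
entire 30–33 nt peak; a policy that reports one best alignment per read
(`-k 1 --best`) retains it. The package implements this whole analysis as
composable, tested R functions: a synthetic reference and read generator
that reproduce the statistical structure of the data, adapter/quality
preprocessing, a seed-based aligner exposing both alignment policies and
both reporting policies, 5'/3'-end and cleavage-site classification, and
negative-binomial GLM tests for age and calorie-restriction (CR) effects.

Because the original study deposited no raw data, the pipeline is exercised
end to end on simulated reads whose generative law matches the study's
reported summary statistics; the published summary tables themselves are
bundled (`study_tables()`) and the reporting operations reproduce the
printed percentages and fold changes exactly from those counts.

## The synthetic reference

`build_synthetic_reference()` scatters tRNA families over random
chromosomes. Copies within a family are exactly identical by default —
identity is the point, since it is what turns tRNA-half reads into
multireads (`family_divergence` can introduce up to two substitutions per
copy to exercise mismatch policies). Default families carry the published
genomic copy numbers of the four dominant isotypes (Gly 29, Val 23, Glu 21,
His 11); the long tail of other isotypes, which contributes <1% of
circulating halves, is collapsed into a single Cys family (copy number 19)
to keep the genome at desk scale. miRNA loci are single copy, which is what
makes the 20–24 nt peak robust to multiread suppression.

Geometry: mature tRNAs are 72 nt with the anticodon starting at mature
position 34. The study's example cloverleaf prints the anticodon at
nucleotides 33–35; with cleavage 1–4 nt upstream of the anticodon that
geometry would give 29–32 nt halves, whereas the observed halves are
30–33 nt. We therefore place the anticodon one base later so that the four
cleavage offsets produce exactly the observed 30–33 nt lengths; the
anticodon position is a per-family parameter, so either convention can be
simulated. Coordinates are 0-based half-open genomically (BED on disk) and
1-based only inside the mature-tRNA frame, where position 1 is the mature
5' nucleotide on either strand.

The annotation is written as BED6 plus five columns (class, isotype,
anticodon, anticodon position, family id); mature sequences are not stored
but reconstructed from the genome on load, which keeps round-trips
bit-exact and guarantees the sequence/annotation invariants are re-checked
at every load.

## The read simulator

`mixture_spec()` fixes the generative law of one library. Each read draws a
class: 5' half, trace 3' half, trace full-length tRNA, miRNA, or background
genomic fragment (5–48 nt, either strand). A 5' half is an exact prefix of
its family's mature sequence ending `offset` nt upstream of the anticodon,
with `offset` drawn from `cleavage_site_probs`; the genomic locus of record
is uniform among the family's identical copies. The default cleavage
distribution is the exact ratio of the published 30/31/32/33 nt read
counts (23/17/35/26% after integer rounding). The 3' adapter is appended
and the read truncated to 50 nt, then substitution errors are applied at
`seq_error_rate` (default 0.001/base, flat — ligation bias and
modification-dependent RT artifacts are deliberately out of scope).
Qualities are constant Q40; `frac_low_quality` emits degraded-quality reads
to exercise the filter.

`simulate_experiment()` adds the 3×3 design (three mice in each of
young-control, old-control, old-CR). Family weights are multiplied by the
group's effects and by a per-sample gamma multiplier with shape and rate
`1/dispersion`, then exactly `n_reads` reads are assigned multinomially:
family totals are marginally negative-binomial with the requested
dispersion (default 0.1, the magnitude typical of biological replicates in
count models) while sequencing depth stays fixed. The tRNA-half compartment
as a whole grows or shrinks with its families' total mass, so a family's
effect moves its absolute count; with depth fixed, strong global shifts
still compress counts compositionally — exactly as in real libraries, and
the reason the testing stage uses TMM-style offsets. Default group effects
mirror the published fold changes (Gly down ~4.5× with age and not restored
by CR, Val down ~2.8× partially restored, His up ~3.8× halved by CR).

What passing tests on these simulations do *not* show about real serum
data: the simulator has no sequence-dependent ligation bias, no RNA
modifications that stall reverse transcription, no isomiR complexity
beyond 3' truncation, and identical family copies by default. One artefact
cuts the other way: the desk-scale genome is roughly 4% tRNA loci by base
(a mammalian genome is nearer 1 in 10^5), so random background fragments
overlap tRNA genes far more often than in real libraries and slightly
inflate internal/3'-end tRNA calls; the tests that assert the >99% 5'
share therefore keep background fragments rare. Claims about the
pipeline's behaviour on real libraries inherit those caveats.

## Preprocessing

The original study preprocessed with FASTX-Toolkit without stating
thresholds, so all parameters are explicit here: the leftmost occurrence of
the 3' adapter — the full adapter anywhere, or a 3'-terminal prefix of at
least `min_overlap = 5` bases — is removed together with everything 3' of
it, tolerating a cutadapt-style 10% mismatch rate over the matched bases.
Reads are kept when at least 80% of bases reach Phred 20 (boundary
inclusive) and the insert is 5–48 nt, the mapped-size range of the study.
Trimming is total and idempotent; the tests compare it against an
exhaustive position-by-position oracle.

## The aligner

Two alignment policies, matching the two bowtie modes whose contrast
reveals the phenomenon:

* `maq_like`: candidate placements come from an exact match of the read's
  first 14 bases (the high-quality 5' end; seed hits from a k-mer hash
  index), extended end-to-end with at most `max_total_mismatches` (default
  2) mismatches. bowtie's quality-weighted ceiling is replaced by this
  plain mismatch budget: simulated qualities are flat and the phenomenon
  under test depends on alignment multiplicity, not quality arithmetic.
* `kdiff`: end-to-end k-difference — every placement with at most `v`
  mismatches anywhere (default `v = 0`; the original study does not state
  its `-v` value, so it is configuration, not a baked-in guess). This
  policy is implemented as an exhaustive scan with early exit (a C++
  kernel), which is exact at desk-scale genome sizes and makes no seeding
  assumption; a seed with mismatches allowed (`seed_mismatches > 0`) in the
  maq-like policy routes through the same exact scan.

The returned set for a read is its *entire* valid set; `n_valid` is the
exact count of placements, never capped. Palindromic placements on both
strands count separately. Reporting is a separate operation:
`best_one` keeps exactly one placement (fewest mismatches, ties broken
deterministically by chromosome, start, strand — bowtie pseudo-randomizes,
but a deterministic tie-break makes multiread count assignment explicit and
testable; a seeded random tie-break is available), and `unique_only` keeps
a read only when `n_valid == 1`. The unit and acceptance tests verify the
valid sets against a brute-force enumeration over every genomic position
and strand for mismatch budgets 0–3 under both policies, and verify the
two defining corollaries: unique-only reads are a subset of best-one reads,
and the 30–33 nt histogram peak collapses by more than 90% under
unique-only reporting while the 20–24 nt miRNA peak survives.

SAM output is minimal but standard: `@SQ` headers, FLAG 16 for the minus
strand, `NM` mismatch tags and an `NH`-style tag carrying `n_valid`.

## Annotation and end classification

A reported alignment is assigned the highest-priority feature class among
the features it overlaps by at least one base, with priority
tRNA > miRNA > rRNA > other small RNA > repeat (the study treats tRNA/miRNA
annotation as primary and drops repeat-class reads from further analysis;
reads assigned to the repeat class are likewise excluded from all
downstream tRNA statistics here). Genic classes require the feature's
strand; repeats are strandless; both choices are configurable because the
original bedtools invocation details are unstated.

A tRNA-overlapping read is `tRNA_5p` iff its 5' terminus lies within
`tol5 = 2` nt of mature position 1, `tRNA_3p` iff its 3' terminus lies
within `tol3 = 2` nt of the mature 3' end, else internal; the end-terminus
rule is one consistent reading of "overlap with the 5' end" and the
tolerance accommodates simulated 5'-end raggedness while keeping classes
crisp. For 5' halves the mature position of the 3' terminal base is the
cleavage position, reported relative to the anticodon
(`offset = anticodon_pos − cleavage_pos`, so offsets 1–4 sit upstream of
the anticodon). A background genomic fragment that happens to start at a
tRNA 5' end is, by design, a genuine `tRNA_5p` call — the classifier sees
alignments, not provenance.

## Differential abundance

Counting uses best-one reporting, so each read increments exactly one
locus; with identical family copies and the deterministic tie-break, a
family's multireads all land on its lexicographically first copy. This
makes explicit what bowtie's randomized placement leaves unknowable (the
published per-locus table lists near-identical values for identical-sequence
loci, implying per-locus counting of multireads; which copy received them
is arbitrary either way).

The model is the standard NB log-linear GLM with one mean per experimental
group and log effective-library-size offsets (raw library size × TMM
factor; TMM here is the trimmed mean of M-values with 30%/5% tails and the
median-library sample as reference, scaled to geometric mean one). The CPM
filter keeps a locus when its *group-mean* CPM reaches 500 in at least one
group — the published filter says "in at least one of the 3 experimental
groups" without defining the group statistic; a per-sample-max variant is
available behind a flag.

Dispersion: the common value maximizes the Cox–Reid adjusted profile
likelihood pooled over loci, evaluated on a 30-point log grid from 1e-4 to
4 with golden-section refinement; tagwise values are shrunk toward the
common one by weighted likelihood (locus APL plus `prior_df / residual_df`
times the mean APL, prior df 10). This captures the model class of the
published edgeR analysis at desk scale without its full empirical-Bayes
machinery; at fixed dispersion the package's likelihood-ratio statistics
agree with edgeR's to ~1e-6, which the tests assert as an independent
cross-check. Each contrast (age: old vs young control; CR: old CR vs old
control) is a 1-df likelihood-ratio chi-square against the model merging
the contrasted groups. Non-converged fits surface as `NA` p-values.

Fold changes follow the signed convention (ratio if ≥1, else minus its
reciprocal, printed to one decimal). Tables report both the raw
group-mean-ratio FC and the model-based FC: the two agree on some published
rows (Gly-GCC, Lys-CTT, Val-AAC) and differ slightly on others (His-GTG
prints 3.8 where the raw mean ratio gives 3.7), so both are shown.
BH q-values are reported, but tables rank by raw p as the published table
does.

## Numerical choices and degenerate inputs

* Chromosomes are concatenated with 64-base `N` separators for the scan
  kernel; placements touching a separator are dropped after decoding, so no
  read (≤48 nt, budgets ≤3) can bridge chromosomes.
* Zero-length trimmed reads are legal values and fall to the length filter.
* All-zero loci are excluded from dispersion estimation and carry the
  common dispersion; a design with one sample per group has no residual df
  and errors unless the user fixes the dispersion explicitly.
* Both group means zero gives an `NA` fold change (flagged row); zero
  reference with positive alternative gives `Inf` rather than a fabricated
  number.
* Every randomized stage takes one named seed; equal seeds give
  byte-identical FASTQ/BED/FASTA outputs and identical pipeline manifests
  (MD5-checksummed).

## Problem sizes

The shipped tests run the full grid on 10^5-read simulations for the
two-peak phenomenon and classifier-recovery checks, brute-force oracle
comparison of ~200 reads on a ≤100 kb genome at mismatch budgets 0–3, a
1000-locus null calibration of the LRT (3 vs 3, dispersion 0.1), dispersion
recovery at 200 (Poisson) and 500 (NB) loci, and 20 replicate simulations
of the 3.75× age effect; these sizes were chosen so the whole suite runs on
a laptop in minutes while leaving the statistical assertions sharp (99%
binomial confidence bands, Kolmogorov–Smirnov at α = 0.01).

## Known limitations

* The aligner supports substitutions only — no indels, no quality-sum
  thresholds, no FM-index; it is exact and exhaustive rather than fast, and
  genomes are expected to be megabase-scale at most.
* tRF-1/CCA-end fragment taxonomy, isomiR analysis and coverage plots are
  out of scope, as are all wet-lab validations of the original study.
* The published serum percentages (Gly 46%/Val 44%, >99% 5' share) are
  emergent properties of data that were never deposited; the pipeline
  reproduces them only as properties of simulations parameterized to match,
  and reproduces exactly those numbers the study printed as counts.
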