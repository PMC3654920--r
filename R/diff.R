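#' Per-locus count matrix from annotated reads
#'
#' Counts tRNA-classified reads (5', 3' and internal) at their assigned
#' locus, per sample. Reads must come from single-placement reporting
#' (`best_one`): each read contributes to exactly one locus, so column sums
#' equal the per-sample tRNA read counts.
#'
#' @param annotations Tibble of [annotate_alignments()] rows with an added
#'   `sample` column (all samples stacked).
#' @param design Tibble with `sample`, `group`.
#' @param lib_sizes Named numeric vector of library sizes (total mapped reads
#'   per sample); defaults to the number of annotated reads per sample.
#' @param loci Optional character vector fixing the locus universe (defaults
#'   to the loci observed).
#' @return A `count_matrix` object: list with `counts` (integer matrix, loci
#'   x samples), `samples` (tibble `sample`, `group`, `lib_size`,
#'   `norm_factor`).
#' @export
count_loci <- function(annotations, design, lib_sizes = NULL, loci = NULL) {
  stopifnot("sample" %in% names(annotations))
  dup <- annotations %>% count(.data$sample, .data$read_id) %>% filter(n > 1L)
  if (nrow(dup)) {
    abort(paste0("duplicate read_id within a sample (", dup$read_id[1],
                 "): counts require one reported alignment per read"),
          class = "trnahalves_integrity_error")
  }
  if (is.null(lib_sizes)) {
    lib_sizes <- annotations %>% count(.data$sample) %>%
      { setNames(.$n, .$sample) }
  }
  tr <- annotations %>%
    filter(.data$feature_class %in% c("tRNA_5p", "tRNA_3p", "tRNA_internal"))
  if (is.null(loci)) loci <- sort(unique(tr$locus_id))
  counts <- matrix(0L, nrow = length(loci), ncol = nrow(design),
                   dimnames = list(loci, design$sample))
  if (nrow(tr)) {
    tab <- tr %>% count(.data$locus_id, .data$sample)
    counts[cbind(match(tab$locus_id, loci), match(tab$sample, design$sample))] <-
      tab$n
  }
  samples <- design %>%
    mutate(lib_size = as.numeric(lib_sizes[design$sample]), norm_factor = 1)
  if (any(is.na(samples$lib_size) | samples$lib_size <= 0)) {
    abort("every sample needs a positive library size",
          class = "trnahalves_validation_error")
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' Assemble a count matrix directly from counts
#'
#' @param counts Integer matrix, loci x samples.
#' @param design Tibble with `sample`, `group` matching the columns.
#' @param lib_sizes Library sizes; default column sums.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts, design, lib_sizes = colSums(counts)) {
  stopifnot(ncol(counts) == nrow(design), all(counts >= 0),
            all(lib_sizes > 0))
  colnames(counts) <- design$sample
  structure(list(counts = counts,
                 samples = mutate(as_tibble(design),
                                  lib_size = as.numeric(lib_sizes),
                                  norm_factor = 1)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " loci x ", ncol(x$counts),
      " samples\n", sep = "")
  print(x$samples)
  invisible(x)
}

#' Counts per million
#'
#' `cpm = count / library_size * 1e6`, using raw library sizes (normalization
#' factors affect model offsets, not the cpm filter).
#'
#' @param cm A `count_matrix`.
#' @return Numeric matrix of CPM values.
#' @export
cpm_matrix <- function(cm) {
  if (any(cm$samples$lib_size <= 0)) {
    abort("zero library size", class = "trnahalves_validation_error")
  }
  sweep(cm$counts, 2, cm$samples$lib_size, "/") * 1e6
}

#' Drop low-abundance loci by group-wise CPM
#'
#' A locus is kept iff its mean CPM reaches `min_cpm` in at least one
#' experimental group (the published filter: minimum 500 cpm in at least one
#' of the 3 groups). `stat = "sample_max"` instead requires a single sample
#' at `min_cpm`.
#'
#' @param cm A `count_matrix`.
#' @param min_cpm Threshold (default 500).
#' @param stat Group statistic: `"group_mean"` (default) or `"sample_max"`.
#' @return The filtered `count_matrix`.
#' @export
filter_low <- function(cm, min_cpm = 500, stat = c("group_mean", "sample_max")) {
  stat <- match.arg(stat)
  cpm <- cpm_matrix(cm)
  groups <- unique(cm$samples$group)
  per_group <- vapply(groups, function(g) {
    cols <- cm$samples$group == g
    if (stat == "group_mean") rowMeans(cpm[, cols, drop = FALSE])
    else apply(cpm[, cols, drop = FALSE], 1, max)
  }, numeric(nrow(cpm)))
  keep <- apply(matrix(per_group, nrow = nrow(cpm)), 1, max) >= min_cpm
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between each sample and a reference sample (the
#' one whose library size is closest to the median), trimming 30% of the
#' log-ratios and 5% of the log-abundances at each tail; factors are scaled
#' to have geometric mean 1. Effective library size = raw size x factor.
#'
#' @param cm A `count_matrix`.
#' @param logratio_trim,abundance_trim Tail-trim fractions.
#' @return The `count_matrix` with `samples$norm_factor` filled in.
#' @export
tmm_normalize <- function(cm, logratio_trim = 0.3, abundance_trim = 0.05) {
  y <- cm$counts
  lib <- cm$samples$lib_size
  ref <- which.min(abs(lib - median(lib)))
  f <- vapply(seq_len(ncol(y)), function(s) {
    if (s == ref) return(1)
    ok <- y[, s] > 0 & y[, ref] > 0
    if (!any(ok)) return(1)
    p_s <- y[ok, s] / lib[s]
    p_r <- y[ok, ref] / lib[ref]
    M <- log2(p_s / p_r)
    A <- 0.5 * log2(p_s * p_r)
    n <- length(M)
    keep <- rank(M) > floor(n * logratio_trim) &
      rank(M) <= n - floor(n * logratio_trim) &
      rank(A) > floor(n * abundance_trim) &
      rank(A) <= n - floor(n * abundance_trim)
    if (!any(keep)) return(1)
    2^mean(M[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  cm$samples$norm_factor <- f
  cm
}

# One NB GLM fit at fixed dispersion phi; X has full column rank.
nb_fit_one <- function(X, y, phi, offset) {
  theta <- if (phi > 0) 1 / phi else 1e8
  fam <- MASS::negative.binomial(theta = theta)
  fit <- suppressWarnings(glm.fit(X, y, family = fam, offset = offset,
                                  control = list(maxit = 50)))
  mu <- pmax(fit$fitted.values, 1e-10)
  ll <- sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X, X * w)
  cr <- 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  list(mu = mu, deviance = fit$deviance, coef = fit$coefficients,
       converged = fit$converged, ll = ll, apl = ll - as.numeric(cr))
}

apl_matrix <- function(y, X, offset, phi_grid) {
  vapply(phi_grid, function(phi) {
    vapply(seq_len(nrow(y)), function(g) {
      nb_fit_one(X, y[g, ], phi, offset)$apl
    }, numeric(1))
  }, numeric(nrow(y)))
}

#' Estimate NB dispersions (common + tagwise)
#'
#' Common dispersion maximizes the Cox-Reid adjusted profile likelihood
#' pooled over loci on a log-spaced grid (with local refinement); tagwise
#' dispersions are shrunk toward the common value by weighted likelihood:
#' each locus maximizes `APL_g(phi) + prior_n * mean_APL(phi)` with
#' `prior_n = prior_df / residual_df`.
#'
#' @param cm A `count_matrix` (filtered; all-zero loci are excluded from
#'   estimation and reported with the common dispersion).
#' @param prior_df Shrinkage prior degrees of freedom (default 10).
#' @param phi_grid Dispersion grid (default 30 points, 1e-4 to 4).
#' @return List with `common` (scalar), `tagwise` (named by locus), and the
#'   grid diagnostics.
#' @export
estimate_dispersion <- function(cm, prior_df = 10,
                                phi_grid = exp(seq(log(1e-4), log(4),
                                                   length.out = 30))) {
  X <- design_matrix(cm)
  df_resid <- ncol(cm$counts) - ncol(X)
  if (df_resid <= 0) {
    abort(paste0("no residual degrees of freedom (", ncol(cm$counts),
                 " samples for ", ncol(X), " parameters); supply a fixed",
                 " dispersion to fit_and_test() instead"),
          class = "trnahalves_validation_error")
  }
  off <- log(cm$samples$lib_size * cm$samples$norm_factor)
  nz <- rowSums(cm$counts) > 0
  y <- cm$counts[nz, , drop = FALSE]
  apl <- apl_matrix(y, X, off, phi_grid)
  pooled <- colMeans(apl)
  i0 <- which.max(pooled)
  lo <- phi_grid[max(1L, i0 - 1L)]
  hi <- phi_grid[min(length(phi_grid), i0 + 1L)]
  common <- optimize(function(phi) {
    mean(vapply(seq_len(nrow(y)), function(g) {
      nb_fit_one(X, y[g, ], phi, off)$apl
    }, numeric(1)))
  }, interval = c(lo, hi), maximum = TRUE)$maximum

  prior_n <- prior_df / df_resid
  wl <- apl + prior_n * matrix(pooled, nrow = nrow(y), ncol = length(phi_grid),
                               byrow = TRUE)
  tg <- phi_grid[apply(wl, 1, which.max)]
  tagwise <- setNames(rep(common, nrow(cm$counts)), rownames(cm$counts))
  tagwise[rownames(y)] <- tg
  list(common = common, tagwise = tagwise,
       phi_grid = phi_grid, pooled_apl = pooled)
}

design_matrix <- function(cm) {
  g <- factor(cm$samples$group,
              levels = unique(cm$samples$group))
  X <- stats::model.matrix(~ 0 + g)
  colnames(X) <- levels(g)
  X
}

#' Signed fold change between two group means
#'
#' `r = mean_alt / mean_ref`, reported as `r` when `r >= 1` and `-1/r`
#' otherwise (tables round it to one decimal). Antisymmetric whenever
#' `|FC| > 1`. Both means zero yields `NA` (flagged row).
#'
#' @param mean_ref,mean_alt Group means (vectorized).
#' @return Signed fold change(s).
#' @export
signed_fold_change <- function(mean_ref, mean_alt) {
  r <- mean_alt / mean_ref
  out <- ifelse(r >= 1, r, -1 / r)
  out[mean_ref == 0 & mean_alt == 0] <- NA_real_
  out[mean_ref == 0 & mean_alt > 0] <- Inf
  out
}

#' Benjamini-Hochberg adjustment
#'
#' @param pvalues Raw p-values.
#' @return BH step-up q-values (monotone in p).
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Fit NB GLMs and run likelihood-ratio tests for the age and CR contrasts
#'
#' Each locus gets a negative-binomial log-linear model with a group mean per
#' experimental group and log effective-library-size offsets, fit by IRLS at
#' its (tagwise) dispersion. Each contrast is tested by a likelihood-ratio
#' chi-square with 1 df against the model that merges the two contrasted
#' groups. Contrasts: age = old_control vs young_control; CR = old_CR vs
#' old_control.
#'
#' @param cm A (filtered) `count_matrix`.
#' @param dispersion Result of [estimate_dispersion()], or a single numeric
#'   dispersion used for every locus.
#' @param contrasts Named list of `c(ref, alt)` group pairs.
#' @return A `trna_diff` object; `tidy()` it for the per-locus table (group
#'   mean counts, mean-ratio and model-based signed FC, LRT p and BH q per
#'   contrast), ranked by the first contrast's p-value.
#' @export
fit_and_test <- function(cm, dispersion = NULL,
                         contrasts = list(
                           age = c("young_control", "old_control"),
                           cr = c("old_control", "old_CR"))) {
  if (is.null(dispersion)) dispersion <- estimate_dispersion(cm)
  phi <- if (is.numeric(dispersion) && length(dispersion) == 1L) {
    setNames(rep(dispersion, nrow(cm$counts)), rownames(cm$counts))
  } else {
    dispersion$tagwise[rownames(cm$counts)]
  }
  X <- design_matrix(cm)
  off <- log(cm$samples$lib_size * cm$samples$norm_factor)
  groups <- cm$samples$group
  loci <- rownames(cm$counts)

  group_means <- vapply(unique(groups), function(g) {
    rowMeans(cm$counts[, groups == g, drop = FALSE])
  }, numeric(nrow(cm$counts)))
  group_means <- matrix(group_means, nrow = nrow(cm$counts),
                        dimnames = list(loci, unique(groups)))

  res <- tibble(locus = loci)
  for (g in colnames(group_means)) {
    res[[paste0("mean_", g)]] <- unname(group_means[, g])
  }

  fulls <- lapply(seq_along(loci), function(i) {
    nb_fit_one(X, cm$counts[i, ], phi[i], off)
  })

  for (cn in names(contrasts)) {
    ref <- contrasts[[cn]][1]
    alt <- contrasts[[cn]][2]
    stopifnot(all(c(ref, alt) %in% colnames(X)))
    merged <- ifelse(groups %in% c(ref, alt), "merged", groups)
    # plain indicator columns: model.matrix() would choke when merging
    # leaves a single level (two-group designs)
    Xr <- vapply(unique(merged), function(l) as.numeric(merged == l),
                 numeric(length(merged)))
    Xr <- matrix(Xr, nrow = length(merged),
                 dimnames = list(NULL, unique(merged)))
    stat <- numeric(length(loci))
    pval <- numeric(length(loci))
    fc_model <- numeric(length(loci))
    ok <- logical(length(loci))
    for (i in seq_along(loci)) {
      f1 <- fulls[[i]]
      f0 <- nb_fit_one(Xr, cm$counts[i, ], phi[i], off)
      stat[i] <- max(0, f0$deviance - f1$deviance)
      pval[i] <- pchisq(stat[i], df = 1, lower.tail = FALSE)
      fc_model[i] <- {
        lr <- f1$coef[alt] - f1$coef[ref]
        r <- exp(lr)
        if (r >= 1) r else -1 / r
      }
      ok[i] <- f1$converged && f0$converged
    }
    pval[!ok] <- NA_real_
    res[[paste0(cn, "_fc")]] <- unname(signed_fold_change(group_means[, ref],
                                                          group_means[, alt]))
    res[[paste0(cn, "_fc_model")]] <- fc_model
    res[[paste0(cn, "_p")]] <- pval
    res[[paste0(cn, "_q")]] <- bh_adjust(pval)
  }
  first_p <- paste0(names(contrasts)[1], "_p")
  res <- arrange(res, .data[[first_p]])
  structure(list(table = res, dispersion = phi, contrasts = contrasts,
                 samples = cm$samples),
            class = "trna_diff")
}

#' @export
print.trna_diff <- function(x, ...) {
  cat("<trna_diff> ", nrow(x$table), " loci, contrasts: ",
      paste(names(x$contrasts), collapse = ", "), "\n", sep = "")
  print(x$table, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-locus differential-abundance table
#' @param x A `trna_diff`.
#' @param ... Unused.
#' @export
tidy.trna_diff <- function(x, ...) x$table

#' One-row summary of a differential-abundance fit
#' @param x A `trna_diff`.
#' @param ... Unused.
#' @export
glance.trna_diff <- function(x, ...) {
  pcols <- paste0(names(x$contrasts), "_q")
  out <- tibble(n_loci = nrow(x$table),
                median_dispersion = median(x$dispersion))
  for (cn in names(x$contrasts)) {
    out[[paste0("n_sig_", cn)]] <-
      sum(x$table[[paste0(cn, "_q")]] <= 0.05, na.rm = TRUE)
  }
  out
}
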