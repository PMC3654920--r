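fake_annotations <- function(sample, loci_counts, n_other = 0L) {
  rows <- list()
  i <- 0L
  for (locus in names(loci_counts)) {
    n <- loci_counts[[locus]]
    if (n == 0) next
    rows[[locus]] <- tibble::tibble(
      sample = sample,
      read_id = sprintf("%s_r%05d", sample, i + seq_len(n)),
      feature_class = "tRNA_5p", locus_id = locus,
      read_len = 32L, cleavage_pos = 32L)
    i <- i + n
  }
  if (n_other > 0) {
    rows[["other"]] <- tibble::tibble(
      sample = sample,
      read_id = sprintf("%s_x%05d", sample, seq_len(n_other)),
      feature_class = "miRNA", locus_id = NA_character_,
      read_len = 22L, cleavage_pos = NA_integer_)
  }
  dplyr::bind_rows(rows)
}

test_that("locus counting conserves tRNA reads and rejects duplicate ids", {
  des <- tibble::tibble(sample = c("a", "b"),
                        group = c("young_control", "old_control"))
  ann <- dplyr::bind_rows(
    fake_annotations("a", c(L1 = 100L), n_other = 20L),
    fake_annotations("b", c(L1 = 40L, L2 = 10L), n_other = 5L))
  cm <- count_loci(ann, des)
  expect_equal(unname(cm$counts["L1", ]), c(100L, 40L))
  expect_equal(unname(colSums(cm$counts)), c(100L, 50L))
  expect_equal(cm$samples$lib_size, c(120, 55))  # all annotated reads

  dup <- dplyr::bind_rows(ann, ann[1, ])
  expect_error(count_loci(dup, des), class = "trnahalves_integrity_error")
})

test_that("cpm arithmetic and the group-mean filter match the stated rules", {
  des <- tibble::tibble(sample = paste0("s", 1:6),
                        group = rep(c("young_control", "old_control",
                                      "old_CR"), each = 2))
  counts <- rbind(
    hi_young = c(600, 600, 10, 10, 10, 10),
    low_all  = c(499, 499, 499, 499, 499, 499),
    hi_cr    = c(0, 0, 0, 0, 700, 800),
    mid      = c(250, 250, 250, 250, 250, 250),
    zero     = c(0, 0, 0, 0, 0, 0))
  cm <- count_matrix(counts, des, lib_sizes = rep(1e6, 6))
  cpm <- cpm_matrix(cm)
  expect_equal(cpm["hi_young", 1], 600)
  expect_equal(unname(cpm_matrix(count_matrix(matrix(123, 1, 6,
                                                     dimnames = list("x", NULL)),
                                              des, lib_sizes = rep(2e6, 6)))[1, 1]),
               61.5)
  kept <- filter_low(cm, min_cpm = 500)
  expect_setequal(rownames(kept$counts), c("hi_young", "hi_cr"))
  # boundary: group means of 499.x cpm are dropped
  expect_false("low_all" %in% rownames(kept$counts))
})

test_that("signed fold change reproduces the published convention", {
  expect_equal(round(signed_fold_change(16868, 3739), 1), -4.5)
  expect_equal(signed_fold_change(5, 5), 1)
  # the mean-ratio convention gives 3.7 where the published model-based value
  # is 3.8: a documented divergence between raw-mean and model fold changes
  expect_equal(round(signed_fold_change(797, 2988), 1), 3.7)
  # antisymmetry whenever |FC| > 1
  set.seed(61)
  a <- runif(50, 1, 1000); b <- runif(50, 1, 1000)
  fc <- signed_fold_change(a, b)
  flip <- signed_fold_change(b, a)
  nz <- abs(fc) > 1
  expect_equal(fc[nz], -flip[nz])
  expect_true(is.na(signed_fold_change(0, 0)))
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(62)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("dispersion estimation recovers the truth and guards the degenerate design", {
  set.seed(63)
  des <- default_design()
  # Poisson counts: estimated common dispersion collapses toward zero
  yp <- t(sapply(1:200, function(g) rpois(9, lambda = 300)))
  rownames(yp) <- paste0("P", 1:200)
  dp <- estimate_dispersion(count_matrix(yp, des))
  expect_lte(dp$common, 0.05)
  # gamma-Poisson with phi = 0.2
  yn <- t(sapply(1:500, function(g) rnbinom(9, mu = 300, size = 5)))
  rownames(yn) <- paste0("N", 1:500)
  dn <- estimate_dispersion(count_matrix(yn, des))
  expect_gte(dn$common, 0.1)
  expect_lte(dn$common, 0.3)
  # tagwise values shrink toward the common value
  expect_lt(stats::sd(log(dn$tagwise)), 1)

  one_per_group <- tibble::tibble(sample = c("a", "b", "c"),
                                  group = c("young_control", "old_control",
                                            "old_CR"))
  y1 <- matrix(rpois(30, 100), nrow = 10,
               dimnames = list(paste0("L", 1:10), NULL))
  expect_error(estimate_dispersion(count_matrix(y1, one_per_group)),
               class = "trnahalves_validation_error")
  # ... but a user-fixed dispersion still allows testing
  fit <- fit_and_test(count_matrix(y1, one_per_group), dispersion = 0.1)
  expect_equal(nrow(tidy(fit)), 10L)
})

test_that("identical groups give a null LRT and equal-count loci p of about 1", {
  des <- default_design()
  y <- matrix(rep(c(100, 100, 100, 100, 100, 100, 250, 250, 250), times = 2),
              nrow = 2, byrow = TRUE, dimnames = list(c("L1", "L2"), NULL))
  y["L1", ] <- 100
  fit <- fit_and_test(count_matrix(y, des, lib_sizes = rep(1e5, 9)),
                      dispersion = 0.1)
  tab <- tidy(fit)
  expect_gt(tab$age_p[tab$locus == "L1"], 0.99)
  expect_equal(tab$age_fc[tab$locus == "L1"], 1)
})

test_that("the NB GLM LRT agrees with an independent implementation at fixed dispersion", {
  set.seed(64)
  des <- default_design()
  y <- t(sapply(1:50, function(g) {
    rnbinom(9, mu = exp(rnorm(1, log(400), 1)), size = 10)
  }))
  rownames(y) <- paste0("L", 1:50)
  cm <- count_matrix(y, des)
  tab <- tidy(fit_and_test(cm, dispersion = 0.1))
  tab <- tab[match(rownames(y), tab$locus), ]

  grp <- factor(des$group, levels = c("young_control", "old_control", "old_CR"))
  X <- stats::model.matrix(~ 0 + grp)
  ef <- edgeR::glmFit(y, design = X, dispersion = 0.1,
                      offset = log(colSums(y)), prior.count = 0)
  p_age <- edgeR::glmLRT(ef, contrast = c(-1, 1, 0))$table$PValue
  p_cr <- edgeR::glmLRT(ef, contrast = c(0, -1, 1))$table$PValue
  expect_equal(tab$age_p, p_age, tolerance = 1e-6)
  expect_equal(tab$cr_p, p_cr, tolerance = 1e-6)
})

test_that("filtering before or after testing leaves survivors' statistics unchanged", {
  set.seed(65)
  des <- default_design()
  mu <- c(rep(2000, 10), rep(5, 10))
  y <- t(sapply(mu, function(m) rnbinom(9, mu = m, size = 10)))
  rownames(y) <- paste0("L", 1:20)
  cm <- count_matrix(y, des, lib_sizes = rep(sum(mu), 9))
  all_fit <- tidy(fit_and_test(cm, dispersion = 0.1))
  flt <- filter_low(cm, min_cpm = 500)
  flt_fit <- tidy(fit_and_test(flt, dispersion = 0.1))
  joined <- dplyr::inner_join(flt_fit, all_fit, by = "locus",
                              suffix = c("_f", "_a"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$age_p_f, joined$age_p_a)
  expect_equal(joined$age_fc_f, joined$age_fc_a)
})

test_that("TMM factors are near one for exchangeable libraries with geometric mean one", {
  set.seed(66)
  des <- default_design()
  y <- t(sapply(1:100, function(g) rnbinom(9, mu = 200, size = 10)))
  rownames(y) <- paste0("L", 1:100)
  cm <- tmm_normalize(count_matrix(y, des))
  f <- cm$samples$norm_factor
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  expect_true(all(abs(log2(f)) < 0.25))
})
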