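test_that("cross-validation folds stratify by breed with near-equal sizes", {
  pan <- hwe_panel(828, 3, seed = 71, breeds = c(rep("A", 600), rep("B", 228)))
  ph <- phenotype_table(records_for(pan, rnorm(828)), pan)
  plan <- make_cv_plan(ph, k = 5, repeats = 2, seed = 7)
  fA <- table(plan$folds[pan$fam$breed == "A", 1])
  expect_true(all(fA == 120))
  fB <- sort(as.integer(table(plan$folds[pan$fam$breed == "B", 1])))
  expect_equal(fB, c(45L, 45L, 46L, 46L, 46L))
  plan2 <- make_cv_plan(ph, k = 5, repeats = 2, seed = 7)
  expect_identical(plan$folds, plan2$folds)
  small <- phenotype_table(records_for(subset_panel(pan, samples = 1:4),
                                       rnorm(4)),
                           subset_panel(pan, samples = 1:4))
  expect_error(make_cv_plan(small, k = 5), "fewer than k")
})

test_that("accuracy is the Pearson correlation with standard conventions", {
  g <- c(1, 2, 3, 4); t_ <- c(2, 1, 4, 3)
  expect_equal(accuracy(g, t_), 0.6)
  expect_equal(accuracy(g, g), 1)
  expect_equal(accuracy(g, -g), -1)
  expect_true(is.na(accuracy(rep(1, 4), t_)))
  # invariances: location shift and positive rescaling of GEBVs
  expect_equal(accuracy(g + 5, t_), accuracy(g, t_))
  expect_equal(accuracy(3 * g, t_), accuracy(g, t_))
})

test_that("unbiasedness is the slope of target on GEBV", {
  set.seed(72)
  g <- rnorm(30); t_ <- 1.4 * g + rnorm(30, 0, 0.3)
  expect_equal(unbiasedness(g, t_), cov(t_, g) / var(g), tolerance = 1e-12)
  expect_equal(unbiasedness(g, g), 1)
  expect_equal(unbiasedness(g, 2 * g), 2)
  expect_equal(unbiasedness(g + 10, t_), unbiasedness(g, t_))
  expect_true(is.na(unbiasedness(rep(2, 30), t_)))
})

test_that("paired t-tests follow the textbook statistic and degenerate rules", {
  a <- c(0.5, 0.6, 0.55, 0.7, 0.62)
  b <- c(0.48, 0.55, 0.57, 0.66, 0.58)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(tstat), df = length(d) - 1)
  expect_equal(paired_ttest(a, b), p_oracle, tolerance = 1e-12)
  expect_equal(paired_ttest(a, a), 1)
  p0 <- paired_ttest(a, a + 0.1)
  expect_equal(as.numeric(p0), 0)
  expect_true(isTRUE(attr(p0, "degenerate")))
  expect_error(paired_ttest(1, 2), "at least 2")
})

test_that("LD-pattern consistency behaves at its reference points", {
  pan <- hwe_panel(120, 40, seed = 73)
  expect_equal(ld_consistency(pan, pan), 1, tolerance = 1e-12)

  # destroying LD in the copy drives the consistency toward zero
  set.seed(74)
  panB <- pan
  for (j in seq_len(ncol(panB$geno)))
    panB$geno[, j] <- panB$geno[sample(nrow(panB$geno)), j]
  expect_lt(abs(ld_consistency(pan, panB)), 0.25)

  # 4-SNP fixture against a brute-force enumeration of the 6 pairs
  GA <- rbind(c(0L,1L,2L,0L), c(1L,1L,0L,2L), c(2L,0L,1L,1L),
              c(0L,2L,2L,0L), c(1L,0L,1L,2L), c(2L,2L,0L,1L))
  GB <- rbind(c(2L,0L,1L,1L), c(0L,1L,2L,0L), c(1L,2L,0L,2L),
              c(2L,1L,1L,0L), c(0L,0L,2L,1L), c(1L,2L,0L,2L))
  pa <- dosage_panel(GA); pb <- dosage_panel(GB)
  r2 <- function(G) {
    out <- c()
    for (i in 1:3) for (j in (i + 1):4)
      out <- c(out, cor(G[, i], G[, j])^2)
    out
  }
  expect_equal(ld_consistency(pa, pb), cor(r2(GA), r2(GB)),
               tolerance = 1e-12)
})

test_that("allele-frequency correlation uses jointly segregating merged-minor SNPs", {
  pan <- hwe_panel(60, 30, seed = 75)
  expect_equal(allele_freq_corr(pan, pan), 1, tolerance = 1e-12)

  # complementary frequencies give -1 when the merged frequency is 1/2
  GA <- rbind(c(0L,0L,0L,1L), c(0L,1L,0L,1L), c(1L,0L,2L,1L), c(1L,1L,2L,1L))
  GB <- 2L - GA
  expect_equal(allele_freq_corr(dosage_panel(GA), dosage_panel(GB)), -1,
               tolerance = 1e-12)

  fa <- colMeans(GA) / 2
  expect_equal(allele_freq_corr(dosage_panel(GA), dosage_panel(GB)),
               cor(fa, 1 - fa), tolerance = 1e-12)
  expect_error(allele_freq_corr(dosage_panel(GA[, 1, drop = FALSE]),
                                dosage_panel(GB[, 1, drop = FALSE])),
               "fewer than 3")
})

test_that("benchmark masking never leaks validation phenotypes", {
  d <- desk_dataset(440, n_ind = c(60, 40), snps_per_chr = 100, n_chr = 1,
                    n_uncorr = 3, n_corr = 2)
  plan <- make_cv_plan(d$pheno, k = 5, repeats = 1, seed = 3)
  val <- which(plan$folds[, 1] == 1)
  # same masked fit whatever the validation phenotypes originally were
  d2 <- d
  oc <- cbind(val, match(d$panel$fam$breed[val], d$pheno$breeds))
  d2$pheno$Y[oc] <- 1e3 * seq_along(val)
  m1 <- mask_phenotypes(d$pheno, d$pheno$ids[val])
  m2 <- mask_phenotypes(d2$pheno, d2$pheno$ids[val])
  expect_identical(m1$Y, m2$Y)
  g <- build_grm(d$panel)
  y1 <- m1$Y[cbind(seq_len(nrow(m1$Y)), match(d$panel$fam$breed, m1$breeds))]
  f1 <- fit_stgblup(y1, matrix(1, length(y1), 1), g)
  y2 <- m2$Y[cbind(seq_len(nrow(m2$Y)), match(d$panel$fam$breed, m2$breeds))]
  f2 <- fit_stgblup(y2, matrix(1, length(y2), 1), g)
  expect_identical(f1$gebv, f2$gebv)
})

test_that("benchmark aggregation matches a naive recompute and flags ties", {
  d <- desk_dataset(441, n_ind = c(60, 40), snps_per_chr = 100, n_chr = 1,
                    n_uncorr = 3, n_corr = 2)
  plan <- make_cv_plan(d$pheno, k = 4, repeats = 2, seed = 5)
  res <- run_benchmark(d, models = c("stgblup", "mtgblup"), cvplan = plan,
                       mcmc = mcmc_config(100, 40, 2, seed = 1))
  for (r in seq_len(nrow(res$summary))) {
    sub <- res$cells[res$cells$model == res$summary$model[r] &
                       res$cells$breed == res$summary$breed[r], ]
    expect_equal(res$summary$accuracy[r], mean(sub$accuracy, na.rm = TRUE))
    expect_equal(res$summary$accuracy_se[r],
                 sd(sub$accuracy, na.rm = TRUE) /
                   sqrt(sum(!is.na(sub$accuracy))))
  }
  expect_true(all(res$cells$accuracy >= -1 & res$cells$accuracy <= 1,
                  na.rm = TRUE))

  # identical GEBVs across "two models" give accuracy difference 0 and p = 1
  a <- res$cells[res$cells$model == "stgblup" & res$cells$breed == "A", ]
  expect_equal(as.numeric(paired_ttest(a$accuracy, a$accuracy)), 1)
})
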