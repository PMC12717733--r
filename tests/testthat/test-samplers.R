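# The exact-mean trick used below: the conditional draws are of the form
# mean(data) + noise(rng), with the noise independent of the data part.
# Drawing twice under the same seed, once with the data zeroed, and
# differencing recovers the conditional mean exactly (no Monte-Carlo error).

test_that("prior construction follows the scale-matrix formulas", {
  # 10 blocks x 10 SNPs, every SNP at frequency 0.5 so each block has
  # sum 2p(1-p) = 5; phenotypic variance exactly 1 in both breeds
  G <- matrix(rep(c(0L, 0L, 0L, 2L, 2L, 2L), 100), 6, 100)
  pan <- dosage_panel(G, breeds = c("A", "B"))
  ph <- phenotype_table(records_for(pan, c(0, 1, 2, 5, 6, 7)), pan)
  bm <- partition_fixed(c(chr1 = 100L), 10L)
  pr <- build_priors(ph, pan, bm, h2 = 0.5)
  expect_equal(pr$df, 6)                       # 4 + p with p = 2
  expect_equal(pr$P, diag(2), ignore_attr = TRUE)
  for (i in 1:10)
    expect_equal(pr$B[[i]], 0.002 * diag(2),   # 0.5 I / (10 * 5 * 5)
                 ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(pr$R_p, 0.1 * diag(2),          # 0.5 I / 5
               ignore_attr = TRUE, tolerance = 1e-12)
  # zero-variance breed is rejected
  ph2 <- phenotype_table(records_for(pan, c(0, 1, 2, 5, 5, 5)), pan)
  expect_error(build_priors(ph2, pan, bm), "zero phenotypic variance")
})

test_that("fixed-effect conditional mean equals the dense GLS oracle", {
  set.seed(101)
  n <- 6; p <- 2
  X <- cbind(1, c(0, 1, 0, 1, 1, 0))
  colnames(X) <- c("mean", "sex")
  Ystar <- matrix(rnorm(n * p, 2), n, p)
  R0 <- matrix(c(1.3, 0.5, 0.5, 0.9), 2)
  # dense oracle on the np-dimensional system (individual-major stacking)
  Xbig <- kronecker(X, diag(p))
  Rbig <- kronecker(diag(n), R0)
  ybig <- as.vector(t(Ystar))
  bet <- solve(t(Xbig) %*% solve(Rbig) %*% Xbig,
               t(Xbig) %*% solve(Rbig) %*% ybig)
  oracle <- t(matrix(bet, p, ncol(X)))
  set.seed(5); d1 <- sample_fixed_effects(Ystar, X, R0)
  set.seed(5); d0 <- sample_fixed_effects(0 * Ystar, X, R0)
  expect_equal(d1 - d0, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # single trait, intercept only, R = I: mean is the sample mean
  y1 <- matrix(rnorm(8), 8, 1)
  set.seed(6); e1 <- sample_fixed_effects(y1, matrix(1, 8, 1), diag(1))
  set.seed(6); e0 <- sample_fixed_effects(0 * y1, matrix(1, 8, 1), diag(1))
  expect_equal(as.numeric(e1 - e0), mean(y1), tolerance = 1e-12)

  # rank-deficient design names the aliased column
  Xbad <- cbind(mean = 1, dup = rep(1, 6))
  expect_error(sample_fixed_effects(Ystar, Xbad, R0), "dup")
})

test_that("per-SNP effect conditional matches the scalar ridge oracle", {
  m <- matrix(c(0, 1, 2, 1, 0), 5, 1)
  ydag <- c(0.3, -1.2, 2.1, 0.4, -0.6)
  s2e <- 1; s2a <- 0.5
  oracle <- drop((crossprod(m) / s2e + 1 / s2a)^-1 * crossprod(m, ydag) / s2e)
  A0 <- matrix(0, 1, 1)
  set.seed(7)
  d1 <- sample_block_effects(m, A0, matrix(ydag, 5, 1),
                             matrix(s2a), matrix(s2e))
  set.seed(7)
  d0 <- sample_block_effects(m, A0, matrix(0, 5, 1),
                             matrix(s2a), matrix(s2e))
  expect_equal(drop(d1$A - d0$A), oracle, tolerance = 1e-12)
  # residuals stay consistent: E_new = E_old - m * a_new
  expect_equal(drop(d1$E), ydag - m[, 1] * drop(d1$A), tolerance = 1e-12)

  # flat-prior limit reproduces OLS
  ols <- drop(crossprod(m, ydag) / crossprod(m))
  set.seed(8)
  f1 <- sample_block_effects(m, A0, matrix(ydag, 5, 1),
                             matrix(1e6), matrix(s2e))
  set.seed(8)
  f0 <- sample_block_effects(m, A0, matrix(0, 5, 1),
                             matrix(1e6), matrix(s2e))
  expect_equal(drop(f1$A - f0$A), ols, tolerance = 1e-4)

  # zero corrected phenotype gives zero posterior mean for all SNPs/breeds
  G2 <- matrix(c(0.4, 0.1, 0.1, 0.3), 2)
  M2 <- matrix(sample(0:2, 12 * 3, TRUE), 12, 3)
  set.seed(9)
  z1 <- sample_block_effects(M2, matrix(0, 3, 2), matrix(0, 12, 2),
                             G2, diag(2))
  set.seed(9)
  z0 <- sample_block_effects(M2, matrix(0, 3, 2), matrix(0, 12, 2),
                             G2, diag(2))
  expect_equal(z1$A, z0$A, tolerance = 1e-14)   # pure noise, equal seeds
})

test_that("covariance conditionals are inverse-Wishart with the stated parameters", {
  # zero effects: the conditional is exactly IW(df + m_i, B_i)
  B <- matrix(c(0.02, 0.005, 0.005, 0.03), 2)
  set.seed(10); g1 <- sample_block_covariance(matrix(0, 10, 2), B, df = 6)
  set.seed(10); g2 <- rinvwishart(6 + 10, B)
  expect_equal(g1, g2, tolerance = 1e-12)

  # zero residuals: exactly IW(df + n, R_p)
  Rp <- 0.1 * diag(2)
  set.seed(11); r1 <- sample_residual_covariance(matrix(0, 100, 2), Rp, 6)
  set.seed(11); r2 <- rinvwishart(6 + 100, Rp)
  expect_equal(r1, r2, tolerance = 1e-12)

  # Monte-Carlo mean of IW(nu, S) is S / (nu - p - 1)
  set.seed(12)
  A <- matrix(rnorm(20), 10, 2)
  S <- crossprod(A) + B
  nu <- 6 + 10
  draws <- replicate(50000, sample_block_covariance(A, B, 6))
  mn <- apply(draws, 1:2, mean)
  se <- apply(draws, 1:2, sd) / sqrt(50000)
  expect_true(all(abs(mn - S / (nu - 2 - 1)) <= 3 * se))
})

test_that("missing-trait residuals follow the bivariate conditional normal", {
  rho <- 0.6
  R0 <- matrix(c(1, rho, rho, 1), 2)
  obs <- matrix(c(TRUE, FALSE), 1, 2)
  E <- matrix(c(1.5, 0), 1, 2)
  # exact conditional mean by the same-seed differencing trick
  set.seed(13); i1 <- impute_missing_phenotypes(E, R0, obs)
  set.seed(13); i0 <- impute_missing_phenotypes(0 * E, R0, obs)
  expect_equal(i1[1, 2] - i0[1, 2], rho * 1.5, tolerance = 1e-12)  # 0.9
  # conditional variance 1 - rho^2 = 0.64, by simulation
  set.seed(14)
  draws <- replicate(40000, impute_missing_phenotypes(E, R0, obs)[1, 2])
  expect_equal(mean(draws), 0.9, tolerance = 4 * sd(draws) / sqrt(40000))
  expect_equal(var(draws), 0.64, tolerance = 0.02)

  # diagonal R0: no borrowing, conditional mean 0
  set.seed(15); d1 <- impute_missing_phenotypes(E, diag(2), obs)
  set.seed(15); d0 <- impute_missing_phenotypes(0 * E, diag(2), obs)
  expect_equal(d1[1, 2], d0[1, 2], tolerance = 1e-14)

  # fully observed rows are untouched
  E2 <- matrix(rnorm(6), 3, 2)
  expect_identical(impute_missing_phenotypes(E2, R0, matrix(TRUE, 3, 2)), E2)
})
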