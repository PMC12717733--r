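test_that("w is 1 when every column is the same vector", {
  col <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L)
  pan <- dosage_panel(matrix(rep(col, 5), 8, 5))
  prof <- compute_w(pan, "chr1", n_win = 3)
  expect_equal(prof$w_raw[1:4], rep(1, 4))
  expect_true(is.na(prof$w_raw[5]))
})

test_that("w matches the brute-force pair-enumeration oracle on a fixed 8x6 matrix", {
  G <- matrix(c(0, 1, 2, 1, 0, 2, 1, 1,
                1, 1, 2, 0, 0, 2, 2, 1,
                2, 0, 1, 1, 2, 0, 1, 2,
                0, 2, 2, 1, 1, 0, 0, 1,
                1, 0, 1, 2, 2, 1, 0, 0,
                2, 2, 0, 0, 1, 1, 2, 1), 8, 6)
  pan <- dosage_panel(G)
  prof <- compute_w(pan, "chr1", n_win = 2)
  expect_equal(prof$w_raw, w_oracle(G, 2), tolerance = 1e-12)
})

test_that("w equals the oracle on random fixtures of 10-60 SNPs", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- sample(10:60, 1)
    n <- sample(8:20, 1)
    nw <- sample(2:8, 1)
    G <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    pan <- dosage_panel(G)
    expect_equal(compute_w(pan, "chr1", n_win = nw)$w_raw, w_oracle(G, nw),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})

test_that("zero-variance columns are excluded and the pair count drops", {
  set.seed(8)
  G <- matrix(sample(0:2, 8 * 6, replace = TRUE), 8, 6)
  G[, 3] <- 1L   # monomorphic column
  pan <- dosage_panel(G)
  prof <- compute_w(pan, "chr1", n_win = 2)
  expect_equal(prof$w_raw, w_oracle(G, 2), tolerance = 1e-12)
  # the count at k=3 excludes all pairs involving column 3
  G2 <- G
  G2[, 3] <- c(0L, 2L, 1L, 0L, 2L, 1L, 0L, 2L)
  full <- compute_w(dosage_panel(G2), "chr1", n_win = 2)
  expect_lt(prof$m_pairs[3], full$m_pairs[3])
})

test_that("widening the window never undefines w and duplication leaves it unchanged", {
  set.seed(12)
  G <- matrix(sample(0:2, 12 * 25, replace = TRUE), 12, 25)
  G[, 7] <- 2L
  pan <- dosage_panel(G)
  w1 <- compute_w(pan, "chr1", n_win = 3)$w_raw
  w2 <- compute_w(pan, "chr1", n_win = 7)$w_raw
  expect_true(all(!(is.na(w2[1:24]) & !is.na(w1[1:24]))))
  pan2 <- dosage_panel(rbind(G, G))
  expect_equal(compute_w(pan2, "chr1", n_win = 3)$w_raw, w1,
               tolerance = 1e-12)
})

test_that("the smoother reproduces constants and straight lines", {
  prof <- structure(list(chrom = "chr1", w_raw = c(rep(0.5, 30), NA),
                         m_pairs = rep(1L, 31), n_win = 5L),
                    class = "w_profile")
  sm <- smooth_w(prof, spar = 0.2)
  expect_equal(sm$w_smooth[1:30], rep(0.5, 30), tolerance = 1e-8)

  lin <- structure(list(chrom = "chr1",
                        w_raw = c(seq(0.1, 0.9, length.out = 40), NA),
                        m_pairs = rep(1L, 41), n_win = 5L),
                   class = "w_profile")
  sm2 <- smooth_w(lin, spar = 0.2)
  expect_equal(sm2$w_smooth[1:40], lin$w_raw[1:40], tolerance = 1e-8)
})

test_that("smoothing a noisy sinusoid tracks the signal better than the raw curve", {
  set.seed(21)
  x <- seq_len(200)
  signal <- 0.5 + 0.3 * sin(x / 12)
  noisy <- signal + rnorm(200, 0, 0.05)
  prof <- structure(list(chrom = "chr1", w_raw = c(noisy, NA),
                         m_pairs = rep(1L, 201), n_win = 5L),
                    class = "w_profile")
  sm <- smooth_w(prof, spar = 0.2)
  expect_gt(cor(sm$w_smooth[1:200], signal), cor(noisy, signal))
})

test_that("fewer than 4 defined points passes through with a warning", {
  prof <- structure(list(chrom = "chr1", w_raw = c(0.2, 0.5, NA, NA),
                         m_pairs = c(1L, 1L, 0L, 0L), n_win = 2L),
                    class = "w_profile")
  expect_warning(sm <- smooth_w(prof), "smoothing skipped")
  expect_equal(sm$w_smooth, prof$w_raw)
})

test_that("breakpoints sit at interior local minima of the smoothed curve", {
  mkprof <- function(sm) {
    m <- length(sm) + 1L
    structure(list(chrom = "chr1", w_raw = c(rep(0.5, m - 1), NA),
                   m_pairs = rep(1L, m), n_win = 5L,
                   w_smooth = c(sm, NA), spar = 0.2),
              class = "w_profile")
  }
  # strictly increasing: one block
  bm <- find_breakpoints(mkprof(seq(0.1, 0.9, length.out = 20)))
  expect_equal(nrow(bm), 1L)
  expect_equal(c(bm$first, bm$last), c(1L, 21L))

  # V with unique minimum at position 11 of 21 (the 0-based index 10)
  v <- c(seq(1, 0, length.out = 11), seq(0.08, 0.8, length.out = 9))
  bm2 <- find_breakpoints(mkprof(v))
  expect_equal(bm2$first, c(1L, 12L))
  expect_equal(bm2$last, c(11L, 21L))

  # double well (min of two shifted parabolas) vs exhaustive interior scan
  x <- seq_len(60)
  dw <- pmin((x - 15)^2 / 400, (x - 45)^2 / 400) + 0.1
  oracle <- which(vapply(2:59, function(k)
    dw[k] < dw[k - 1] && dw[k] < dw[k + 1], TRUE)) + 1L
  bm3 <- find_breakpoints(mkprof(dw))
  expect_equal(bm3$last[-nrow(bm3)], oracle)

  # a low plateau breaks once, at its last index
  pl <- c(5:1, 1, 1, 2:6) / 10
  bm4 <- find_breakpoints(mkprof(pl))
  expect_equal(bm4$last[1], 7L)
  expect_equal(nrow(bm4), 2L)
})

test_that("fixed-size partition fills chromosomes with remainders", {
  bm <- partition_fixed(c(chr1 = 250L), 100L)
  expect_equal(bm$n_snps, c(100L, 100L, 50L))
  bm2 <- partition_fixed(c(chr1 = 50L), 100L)
  expect_equal(bm2$n_snps, 50L)
  bm3 <- partition_fixed(c(chr1 = 120L, chr2 = 80L), 100L)
  expect_equal(bm3$n_snps, c(100L, 20L, 80L))
  expect_equal(bm3$chrom, c("chr1", "chr1", "chr2"))
  # block boundaries coincide with chromosome ends
  expect_equal(bm3$first[3], 121L)
})

test_that("genome partition composes per-chromosome results and is deterministic", {
  pan <- hwe_panel(30, 80, seed = 31, n_chr = 2)
  bm <- partition_genome(pan, "ld", n_win = 5)
  # equals concatenation of per-chromosome runs
  rows <- list()
  off <- 0L
  for (ch in c("chr1", "chr2")) {
    sub <- find_breakpoints(smooth_w(compute_w(pan, ch, n_win = 5)))
    rows[[ch]] <- data.frame(first = off + sub$first, last = off + sub$last)
    off <- off + sum(sub$n_snps)
  }
  ref <- do.call(rbind, rows)
  expect_equal(bm$first, ref$first)
  expect_equal(bm$last, ref$last)
  expect_identical(bm, partition_genome(pan, "ld", n_win = 5))
})

test_that("every block map tiles its chromosomes exactly", {
  for (seed in 1:4) {
    pan <- hwe_panel(20, sample(40:120, 1), seed = seed + 40, n_chr = 2)
    for (meth in c("ld", "fixed")) {
      bm <- partition_genome(pan, meth, n_win = 4, block_size = 17)
      expect_equal(sum(bm$n_snps), ncol(pan$geno))
      expect_equal(bm$first[1], 1L)
      expect_true(all(diff(bm$first) == bm$n_snps[-nrow(bm)]))
      # chromosome boundaries respected
      for (ch in unique(pan$map$chrom)) {
        cols <- which(pan$map$chrom == ch)
        b <- bm[bm$chrom == ch, ]
        expect_equal(min(b$first), min(cols))
        expect_equal(max(b$last), max(cols))
      }
    }
  }
})

test_that("fixed partition block count follows per-chromosome arithmetic", {
  sizes <- c(chr1 = 3117L, chr2 = 2951L, chr3 = 2404L)
  bm <- partition_fixed(sizes, 100L)
  expect_equal(nrow(bm), sum(ceiling(sizes / 100)))
})
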