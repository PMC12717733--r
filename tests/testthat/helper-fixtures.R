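# fixture builders and independent oracles used across test files

# panel with SNPs drawn under Hardy-Weinberg equilibrium
hwe_panel <- function(n, m, seed = 1, n_chr = 1L, breeds = "A",
                      maf = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  G <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  # ensure polymorphism so downstream QC never trips on tiny n
  for (j in which(apply(G, 2, sd) == 0)) G[1:2, j] <- c(0L, 2L)
  mpc <- ceiling(m / n_chr)
  chrom <- paste0("chr", rep(seq_len(n_chr), each = mpc))[1:m]
  map <- data.frame(id = sprintf("s%05d", 1:m), chrom = chrom,
                    pos = ave(seq_len(m), chrom, FUN = seq_along) * 1000,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  fam <- data.frame(id = sprintf("i%04d", 1:n),
                    breed = sort(rep_len(breeds, n)), stringsAsFactors = FALSE)
  recode_minor(genotype_panel(G, map, fam))
}

# panel from an explicit dosage matrix, single chromosome
dosage_panel <- function(G, breeds = "A", chrom = "chr1") {
  n <- nrow(G); m <- ncol(G)
  map <- data.frame(id = sprintf("s%03d", 1:m), chrom = chrom,
                    pos = seq_len(m) * 1000, a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  fam <- data.frame(id = sprintf("i%03d", 1:n),
                    breed = sort(rep_len(breeds, n)), stringsAsFactors = FALSE)
  genotype_panel(G, map, fam)
}

# brute-force oracle for the windowed LD statistic: enumerate every pair
# (i, j) with i <= k < j, k - i < n_win, j - k <= n_win, j - i <= n_win;
# Pearson-correlate raw dosage columns, square, average. Pairs involving a
# zero-variance column are excluded and the count reduced.
w_oracle <- function(G, n_win) {
  m <- ncol(G)
  w <- rep(NA_real_, m)
  for (k in seq_len(m - 1)) {
    vals <- c()
    for (i in seq_len(k)) for (j in (k + 1):m) {
      if (k - i >= n_win || j - k > n_win || j - i > n_win) next
      if (sd(G[, i]) == 0 || sd(G[, j]) == 0) next
      vals <- c(vals, cor(G[, i], G[, j])^2)
    }
    if (length(vals)) w[k] <- mean(vals)
  }
  w
}

# Hudson's Fst estimator averaged over loci (ratio of averages)
fst_hudson <- function(gA, gB) {
  pa <- colMeans(gA) / 2; pb <- colMeans(gB) / 2
  na <- nrow(gA); nb <- nrow(gB)
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

# two-breed phenotype records on a panel, from explicit values
records_for <- function(panel, values) {
  data.frame(id = panel$fam$id, breed = panel$fam$breed, trait = values,
             stringsAsFactors = FALSE)
}

# small simulated study used by several Gibbs/benchmark tests
desk_dataset <- function(seed, n_ind = c(150, 80), snps_per_chr = 150,
                         n_chr = 2, r_g_mean = 0.8, scenario = "identical",
                         n_uncorr = 6, n_corr = 3, qtl_per_corr = 3) {
  cfg <- two_breed_config(n_ind = n_ind, snps_per_chr = snps_per_chr,
                          n_chr = n_chr, hist_generations = 40,
                          hist_size = 80, seed = seed)
  cfg$arch <- arch_config(n_uncorr = n_uncorr, n_corr = n_corr,
                          qtl_per_corr = qtl_per_corr,
                          r_g_mean = r_g_mean, scenario = scenario)
  suppressWarnings(simulate_dataset(cfg))
}
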