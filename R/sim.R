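#' Simulation configuration
#'
#' Describes a multibreed simulation: a historical random-mating population
#' builds up linkage disequilibrium by drift and recombination; breeds are
#' then founded from it and diverge through breed-specific selection during
#' their formation generations; the analyzed panel is drawn as two
#' individuals per litter from the last three generations. QTL effects are
#' placed on an LD block map with 300 one-QTL uncorrelated blocks plus 10
#' ten-QTL blocks whose effects are correlated across breeds.
#'
#' @param breeds list of [breed_config()] entries.
#' @param arch an [arch_config()].
#' @param n_chr number of chromosomes.
#' @param snps_per_chr SNP loci simulated per chromosome (before
#'   ascertainment of segregating loci).
#' @param chr_length_bp physical chromosome length (bp); genetic length is
#'   `chr_length_morgan`.
#' @param chr_length_morgan genetic chromosome length in Morgan.
#' @param hist_size historical population size (diploids).
#' @param hist_generations historical random-mating generations.
#' @param litter_size offspring per litter during breed formation.
#' @param sel_prop proportion of candidates kept by truncation selection.
#' @param aux_h2 heritability of the auxiliary selection trait used during
#'   breed formation (independent of the analysis trait).
#' @param seed optional seed applied by [simulate_dataset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(breeds, arch = arch_config(), n_chr = 5L,
                       snps_per_chr = 500L, chr_length_bp = 1e8,
                       chr_length_morgan = 1, hist_size = 100L,
                       hist_generations = 100L, litter_size = 8L,
                       sel_prop = 0.5, aux_h2 = 0.3, seed = NULL) {
  stopifnot(length(breeds) >= 1L, litter_size >= 2L,
            sel_prop > 0, sel_prop <= 1)
  structure(list(breeds = breeds, arch = arch, n_chr = as.integer(n_chr),
                 snps_per_chr = as.integer(snps_per_chr),
                 chr_length_bp = chr_length_bp,
                 chr_length_morgan = chr_length_morgan,
                 hist_size = as.integer(hist_size),
                 hist_generations = as.integer(hist_generations),
                 litter_size = as.integer(litter_size),
                 sel_prop = sel_prop, aux_h2 = aux_h2, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @param name breed label.
#' @param gen breed-formation generations.
#' @param sel selection criterion during formation: `"rnd"` (random),
#'   `"phen/h"` (high auxiliary phenotype) or `"phen/l"` (low).
#' @param n_ind individuals emitted for analysis.
#' @param h2 heritability of the analysis trait in this breed.
#' @param mean population mean of the analysis trait in this breed.
#' @export
breed_config <- function(name, gen, sel = c("rnd", "phen/h", "phen/l"),
                         n_ind, h2, mean) {
  sel <- match.arg(sel)
  stopifnot(gen >= 1L, n_ind >= 2L, h2 > 0, h2 <= 1)
  structure(list(name = name, gen = as.integer(gen), sel = sel,
                 n_ind = as.integer(n_ind), h2 = h2, mean = mean),
            class = "breed_config")
}

#' @rdname sim_config
#' @param n_uncorr blocks carrying one QTL with independent effects across
#'   breeds (default 300).
#' @param n_corr blocks carrying `qtl_per_corr` QTLs whose effects are
#'   correlated across breeds (default 10).
#' @param qtl_per_corr QTLs per correlated block (default 10).
#' @param r_g_mean target mean cross-breed effect correlation of the
#'   correlated blocks.
#' @param scenario `"identical"` (every correlated block at `r_g_mean`) or
#'   `"uniform"` (block correlations drawn U(-1, 1) and adjusted so their
#'   mean equals `r_g_mean`).
#' @param corr_pair with 3+ breeds, indices of the breed pair that shares
#'   the correlation (others uncorrelated); default `c(1, 2)`.
#' @export
arch_config <- function(n_uncorr = 300L, n_corr = 10L, qtl_per_corr = 10L,
                        r_g_mean = 0.8, scenario = c("identical", "uniform"),
                        corr_pair = c(1L, 2L)) {
  scenario <- match.arg(scenario)
  stopifnot(abs(r_g_mean) <= 1, n_uncorr >= 0L, n_corr >= 0L)
  structure(list(n_uncorr = as.integer(n_uncorr),
                 n_corr = as.integer(n_corr),
                 qtl_per_corr = as.integer(qtl_per_corr),
                 r_g_mean = r_g_mean, scenario = scenario,
                 corr_pair = as.integer(corr_pair)),
            class = "arch_config")
}

#' Paper-style presets
#'
#' `two_breed_config()`: breed A formed over 40 generations of high
#' phenotypic selection (3000 individuals, h2 0.5, mean 1.0) and breed B
#' over 10 generations of random selection (600 individuals, h2 0.3,
#' mean 0.5). `three_breed_config()`: A (70, rnd, 600, 0.5, 1.5),
#' B (40, phen/h, 600, 0.4, 1.0), C (10, phen/l, 600, 0.3, 0.5).
#' `n_ind` and panel density can be scaled down for desk-scale runs while
#' keeping the formation parameters.
#'
#' @param n_ind override of per-breed individual counts (same order).
#' @param snps_per_chr,n_chr panel density overrides.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
two_breed_config <- function(n_ind = c(3000L, 600L), snps_per_chr = 500L,
                             n_chr = 5L, ...) {
  sim_config(list(
    breed_config("A", 40L, "phen/h", n_ind[1], 0.5, 1.0),
    breed_config("B", 10L, "rnd", n_ind[2], 0.3, 0.5)),
    n_chr = n_chr, snps_per_chr = snps_per_chr, ...)
}

#' @rdname two_breed_config
#' @export
three_breed_config <- function(n_ind = c(600L, 600L, 600L),
                               snps_per_chr = 500L, n_chr = 5L, ...) {
  sim_config(list(
    breed_config("A", 70L, "rnd", n_ind[1], 0.5, 1.5),
    breed_config("B", 40L, "phen/h", n_ind[2], 0.4, 1.0),
    breed_config("C", 10L, "phen/l", n_ind[3], 0.3, 0.5)),
    n_chr = n_chr, snps_per_chr = snps_per_chr, ...)
}

# one gamete from a diploid parent: Poisson crossovers on a Haldane map
# (positions uniform), random starting haplotype. h1/h2 are 0/1 vectors.
.gamete <- function(h1, h2, pos_list, morgan) {
  out <- vector("list", length(pos_list))
  for (ci in seq_along(pos_list)) {
    pos <- pos_list[[ci]]
    k <- stats::rpois(1, morgan)
    start <- stats::rbinom(1, 1, 0.5)
    if (k == 0) {
      idx <- rep(start, length(pos))
    } else {
      bp <- sort(stats::runif(k, 0, max(pos)))
      idx <- (start + findInterval(pos, bp)) %% 2L
    }
    out[[ci]] <- idx
  }
  idx <- unlist(out, use.names = FALSE)
  ifelse(idx == 0L, h1, h2)
}

# matrix of gametes for chosen parent indices (columns of H1/H2 pairs)
.make_offspring <- function(H, parents, pos_list, morgan) {
  # H: 2N x m haplotypes, rows 2i-1, 2i belong to individual i
  n_off <- nrow(parents)
  m <- ncol(H)
  out <- matrix(0L, 2L * n_off, m)
  for (i in seq_len(n_off)) {
    p1 <- parents[i, 1]; p2 <- parents[i, 2]
    out[2L * i - 1L, ] <- .gamete(H[2L * p1 - 1L, ], H[2L * p1, ],
                                  pos_list, morgan)
    out[2L * i, ] <- .gamete(H[2L * p2 - 1L, ], H[2L * p2, ],
                             pos_list, morgan)
  }
  out
}

#' Simulate multibreed genotypes
#'
#' Forward-in-time simulation: (1) a historical random-mating population
#' with recombination and drift builds LD; (2) per-breed founders are drawn
#' from it; (3) each breed goes through its formation generations of litters
#' with truncation selection on an auxiliary phenotype (high, low, or
#' random); (4) the analysis panel takes two individuals per litter from the
#' last three generations, and loci are ascertained to segregate in the
#' merged panel.
#'
#' @param config a `sim_config`.
#' @return A `genotype_panel` containing all breeds, dosages coded as
#'   merged-panel minor-allele counts. The auxiliary-trait effects are
#'   attached as attribute `aux_effects`.
#' @export
simulate_genotypes <- function(config) {
  n_chr <- config$n_chr
  mpc <- config$snps_per_chr
  m <- n_chr * mpc
  pos <- round(seq(1, config$chr_length_bp, length.out = mpc))
  pos_list <- rep(list(pos), n_chr)
  morgan <- config$chr_length_morgan

  # historical population: drift + recombination from linkage-equilibrium start
  N <- config$hist_size
  p0 <- stats::runif(m, 0.1, 0.9)
  H <- matrix(stats::rbinom(2L * N * m, 1L, rep(p0, each = 2L * N)),
              2L * N, m)
  for (g in seq_len(config$hist_generations)) {
    par <- cbind(sample.int(N, N, replace = TRUE),
                 sample.int(N, N, replace = TRUE))
    H <- .make_offspring(H, par, pos_list, morgan)
  }

  # auxiliary selection trait (independent of the analysis trait's QTLs)
  beta_aux <- stats::rnorm(m, 0, 1 / sqrt(m))
  aux_pheno <- function(Hb) {
    n <- nrow(Hb) / 2L
    dose <- Hb[seq(1, 2L * n, 2), , drop = FALSE] +
      Hb[seq(2, 2L * n, 2), , drop = FALSE]
    tbv <- drop(dose %*% beta_aux)
    vt <- stats::var(tbv)
    if (vt <= 0) return(tbv + stats::rnorm(n))
    tbv + stats::rnorm(n, 0, sqrt(vt * (1 - config$aux_h2) / config$aux_h2))
  }

  panels <- list(); fams <- list()
  for (bc in config$breeds) {
    # 2 per litter x 3 generations sets a floor; a minimum litter count
    # keeps the breeding population from collapsing in small runs
    litters <- max(ceiling(bc$n_ind / 6), 20L)
    n_found <- min(N, max(30L, 2L * litters))
    Hb <- H[rep(2L * sample.int(N, n_found) - 1L, each = 2L) +
              c(0L, 1L), , drop = FALSE]
    collected <- list()
    for (g in seq_len(bc$gen)) {
      nb <- nrow(Hb) / 2L
      keep <- max(2L, ceiling(nb * config$sel_prop))
      sel_idx <- switch(bc$sel,
                        "rnd" = sample.int(nb, keep),
                        "phen/h" = order(aux_pheno(Hb),
                                         decreasing = TRUE)[seq_len(keep)],
                        "phen/l" = order(aux_pheno(Hb))[seq_len(keep)])
      par <- matrix(0L, litters * config$litter_size, 2L)
      lit_par <- cbind(sample(sel_idx, litters, replace = TRUE),
                      sample(sel_idx, litters, replace = TRUE))
      for (li in seq_len(litters)) {
        rows <- (li - 1L) * config$litter_size + seq_len(config$litter_size)
        par[rows, 1] <- lit_par[li, 1]
        par[rows, 2] <- lit_par[li, 2]
      }
      Hb <- .make_offspring(Hb, par, pos_list, morgan)
      if (g > bc$gen - 3L) {
        # two individuals per litter
        pick <- unlist(lapply(seq_len(litters), function(li)
          (li - 1L) * config$litter_size +
            sample.int(config$litter_size, 2L)))
        collected[[length(collected) + 1L]] <-
          Hb[rep(2L * pick - 1L, each = 2L) + c(0L, 1L), , drop = FALSE]
      }
    }
    Hc <- do.call(rbind, collected)
    avail <- nrow(Hc) / 2L
    if (avail < bc$n_ind)
      stop("breed ", bc$name, ": requested ", bc$n_ind,
           " individuals but only ", avail, " produced")
    pick <- sample.int(avail, bc$n_ind)
    dose <- Hc[2L * pick - 1L, , drop = FALSE] + Hc[2L * pick, , drop = FALSE]
    paf <- colMeans(dose) / 2
    if (mean(paf %in% c(0, 1)) > 0.5)
      warning("breed ", bc$name, ": more than half of the loci are fixed")
    panels[[bc$name]] <- dose
    fams[[bc$name]] <- data.frame(
      id = sprintf("%s_%04d", bc$name, seq_len(bc$n_ind)),
      breed = bc$name, stringsAsFactors = FALSE)
  }
  geno <- do.call(rbind, panels)
  fam <- do.call(rbind, fams)
  rownames(fam) <- NULL
  af <- colMeans(geno) / 2
  segregating <- af > 0 & af < 1
  geno <- geno[, segregating, drop = FALSE]
  map <- data.frame(
    id = sprintf("snp%05d", which(segregating)),
    chrom = paste0("chr", rep(seq_len(n_chr), each = mpc))[segregating],
    pos = rep(pos, n_chr)[segregating],
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  panel <- recode_minor(genotype_panel(geno, map, fam))
  attr(panel, "aux_effects") <- beta_aux[segregating]
  panel
}

#' Assign QTL effects on a block map
#'
#' Draws the trait architecture: `n_uncorr` blocks get one QTL with
#' independent N(0,1) effects per breed; `n_corr` blocks get
#' `qtl_per_corr` QTLs whose per-breed effects are drawn from a correlated
#' normal with block correlation `r_b` (`r_g_mean` exactly under
#' "identical"; drawn U(-1,1) and shifted, with boundary clipping and
#' re-adjustment, so the block mean equals `r_g_mean` under "uniform").
#' Blocks are drawn without replacement.
#'
#' @param blockmap a `block_map` (from the merged panel used for phenotype
#'   simulation).
#' @param arch an `arch_config`.
#' @param n_breeds number of breeds.
#' @return list with `effects` (m x p matrix, zero off-QTL), `qtl`
#'   (data.frame: block, snp index, type), and `block_r` (assigned
#'   correlation per correlated block).
#' @export
assign_qtl_effects <- function(blockmap, arch, n_breeds) {
  s <- nrow(blockmap)
  p <- n_breeds
  need <- arch$n_uncorr + arch$n_corr
  big <- which(blockmap$n_snps >= arch$qtl_per_corr)
  if (s < need || length(big) < arch$n_corr)
    stop("blockmap has too few (large enough) blocks: need ", need,
         " incl. ", arch$n_corr, " with >= ", arch$qtl_per_corr, " SNPs")
  corr_blocks <- sample(big, arch$n_corr)
  rest <- setdiff(seq_len(s), corr_blocks)
  unc_blocks <- sample(rest, arch$n_uncorr)
  m <- sum(blockmap$n_snps)
  eff <- matrix(0, m, p)
  qtl <- list()
  for (b in unc_blocks) {
    j <- sample(blockmap$first[b]:blockmap$last[b], 1L)
    eff[j, ] <- stats::rnorm(p)
    qtl[[length(qtl) + 1L]] <- data.frame(block = b, snp = j,
                                          type = "uncorrelated")
  }
  block_r <- numeric(0)
  if (arch$n_corr > 0L) {
    block_r <- if (arch$scenario == "identical")
      rep(arch$r_g_mean, arch$n_corr)
    else {
      r <- stats::runif(arch$n_corr, -1, 1)
      for (i in 1:100) {
        delta <- arch$r_g_mean - mean(r)
        if (abs(delta) < 1e-12) break
        free <- if (delta > 0) r < 1 else r > -1
        if (!any(free)) break
        r[free] <- r[free] + delta * length(r) / sum(free)
        r <- pmin(1, pmax(-1, r))
      }
      r
    }
    pair <- arch$corr_pair
    for (ib in seq_along(corr_blocks)) {
      b <- corr_blocks[ib]
      r_b <- block_r[ib]
      js <- sample(blockmap$first[b]:blockmap$last[b], arch$qtl_per_corr)
      x1 <- stats::rnorm(arch$qtl_per_corr)
      z <- stats::rnorm(arch$qtl_per_corr)
      x2 <- r_b * x1 + sqrt(max(0, 1 - r_b^2)) * z
      for (l in seq_len(p)) {
        eff[js, l] <- if (l == pair[1]) x1
        else if (l == pair[2]) x2
        else stats::rnorm(arch$qtl_per_corr)
      }
      qtl[[length(qtl) + 1L]] <- data.frame(block = b, snp = js,
                                            type = "correlated")
    }
  }
  list(effects = eff, qtl = do.call(rbind, qtl), block_r = block_r)
}

#' Simulate phenotypes from assigned effects
#'
#' True breeding values are `dosage x effect`, expressed as deviations from
#' each breed-trait's own-breed mean; per-breed effects are scaled so the
#' in-sample genetic variance equals the breed's h2 (phenotypic variance
#' ~ 1), and phenotype = breed mean + TBV + N(0, var(TBV)(1-h2)/h2).
#'
#' @param panel a `genotype_panel`.
#' @param truth effect assignment from [assign_qtl_effects()].
#' @param breed_cfgs list of `breed_config` in panel breed order.
#' @return list with `pheno` (a `pheno_table`) and `truth` (a `truth_set`:
#'   scaled `effects`, `qtl`, `block_r`, realized `block_r_realized`, `tbv`
#'   matrix (n x p), own-breed `tbv_own`, residual variances, means).
#' @export
simulate_phenotypes <- function(panel, truth, breed_cfgs) {
  breeds <- vapply(breed_cfgs, function(b) b$name, "")
  stopifnot(setequal(breeds, unique(panel$fam$breed)))
  p <- length(breeds)
  eff <- truth$effects
  if (nrow(eff) != ncol(panel$geno))
    stop("effect matrix does not match panel SNP count")
  tbv <- panel$geno %*% eff
  s2e <- numeric(p); mu <- numeric(p)
  for (l in seq_len(p)) {
    bc <- breed_cfgs[[l]]
    rows <- panel$fam$breed == bc$name
    v <- stats::var(tbv[rows, l])
    if (v <= 0) stop("zero genetic variance in breed ", bc$name)
    sc <- sqrt(bc$h2 / v)
    eff[, l] <- eff[, l] * sc
    tbv[, l] <- tbv[, l] * sc
    # breeding values as deviations from the breed-trait's own-breed mean,
    # so the phenotype mean recovers the configured breed mean
    tbv[, l] <- tbv[, l] - mean(tbv[rows, l])
    s2e[l] <- bc$h2 * (1 - bc$h2) / bc$h2   # = 1 - h2 after scaling
    mu[l] <- bc$mean
  }
  names(s2e) <- names(mu) <- breeds
  rec <- list()
  for (l in seq_len(p)) {
    bc <- breed_cfgs[[l]]
    rows <- which(panel$fam$breed == bc$name)
    y <- mu[l] + tbv[rows, l] +
      if (bc$h2 < 1) stats::rnorm(length(rows), 0, sqrt(s2e[l])) else 0
    rec[[l]] <- data.frame(id = panel$fam$id[rows], breed = bc$name,
                           trait = y, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  pheno <- phenotype_table(records, panel, trait = "trait")
  own <- tbv[cbind(seq_len(nrow(tbv)),
                   match(panel$fam$breed, breeds))]
  realized <- if (length(truth$block_r)) {
    vapply(unique(truth$qtl$block[truth$qtl$type == "correlated"]),
           function(b) {
             js <- truth$qtl$snp[truth$qtl$block == b]
             stats::cor(eff[js, 1], eff[js, 2])
           }, 0)
  } else numeric(0)
  ts <- structure(list(effects = eff, qtl = truth$qtl,
                       block_r = truth$block_r,
                       block_r_realized = realized,
                       tbv = tbv, tbv_own = own, breeds = breeds,
                       means = mu, resid_var = s2e),
                  class = "truth_set")
  list(pheno = pheno, truth = ts)
}

#' Simulate a full dataset
#'
#' Genotypes, LD partition of the merged panel, QTL placement and
#' phenotypes, with full truth tracking. With 3+ breeds the partition used
#' for phenotype simulation is built from the genotypes of the correlated
#' breed pair only (the others' trait architecture is uncorrelated).
#'
#' @param config a `sim_config` (its `seed`, if set, is applied first).
#' @param n_win,spar partition parameters, see [partition_genome()].
#' @return list with `panel`, `pheno`, `truth`, `blockmap`.
#' @export
simulate_dataset <- function(config, n_win = 50L, spar = 0.2) {
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- simulate_genotypes(config)
  breeds <- vapply(config$breeds, function(b) b$name, "")
  part_panel <- if (length(breeds) > 2L) {
    pair <- breeds[config$arch$corr_pair]
    subset_panel(panel, samples = panel$fam$breed %in% pair)
  } else panel
  bm <- partition_genome(part_panel, method = "ld", n_win = n_win,
                         spar = spar)
  assign <- assign_qtl_effects(bm, config$arch, length(breeds))
  simres <- simulate_phenotypes(panel, assign, config$breeds)
  list(panel = panel, pheno = simres$pheno, truth = simres$truth,
       blockmap = bm)
}

#' Independent simulation replicates
#'
#' @param config a `sim_config`.
#' @param n_reps number of replicates (default 20).
#' @param seed master seed from which per-replicate seeds are derived.
#' @param ... passed to [simulate_dataset()].
#' @return list of `simulate_dataset()` results.
#' @export
make_replicates <- function(config, n_reps = 20L, seed = 1L, ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  lapply(seq_len(n_reps), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    simulate_dataset(cfg, ...)
  })
}
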