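#' Fit the blockwise multitrait BayesA model by Gibbs sampling
#'
#' Runs the full Gibbs sampler for the multibreed model with block-specific
#' genetic (co)variance. Each cycle updates, in order: imputation of
#' structurally missing breed-trait residuals, fixed effects, all marker
#' effects block by block (one p-variate SNP at a time with incremental
#' residual updates), each block covariance G_i, and the residual covariance
#' R_0. GEBVs are posterior means of the genetic values `M A` accumulated
#' across stored samples.
#'
#' @param pheno a `pheno_table` (validation individuals may be fully
#'   masked; they are imputed and still receive GEBVs).
#' @param panel the merged `genotype_panel`.
#' @param blockmap a `block_map` tiling the panel; supply an LD map for the
#'   LD-block model or a fixed-size map for the fixed comparator.
#' @param priors a `prior_spec`; defaults to [build_priors()] on the inputs.
#' @param config an `mcmc_config`.
#' @param keep_draws store thinned draws of every G_i and R_0 (diagnostics).
#' @param block_order optional permutation of block indices giving the
#'   update order within each cycle (default: map order). The stationary
#'   distribution does not depend on it.
#' @param verbose print progress every 1000 cycles.
#' @return An object of class `mbgp_post`: posterior means `b`, `effects`
#'   (m x p), `G` (p x p x s), `R0`, per-block genetic correlations
#'   `r_block`, `gebv` and `gebv_sd` (n x p), `n_stored`, plus inputs'
#'   metadata.
#' @export
run_gibbs <- function(pheno, panel, blockmap, priors = NULL,
                      config = mcmc_config(), keep_draws = FALSE,
                      block_order = NULL, verbose = FALSE) {
  if (is.null(priors)) priors <- build_priors(pheno, panel, blockmap)
  if (!is.null(config$seed)) set.seed(config$seed)
  breeds <- pheno$breeds
  p <- priors$p
  stopifnot(length(breeds) == p)
  Y <- pheno$Y
  X <- pheno$X
  n <- nrow(Y); q <- ncol(X); m <- ncol(panel$geno)
  if (sum(blockmap$n_snps) != m) stop("blockmap does not tile the panel")
  obs <- !is.na(Y)
  # dosages are column-centered for sampling: this decouples the marker
  # effects from the per-breed means (better mixing geometry) and leaves
  # every reported quantity except an additive GEBV constant unchanged
  M <- sweep(panel$geno, 2, 2 * allele_freq(panel))
  s <- nrow(blockmap)
  df <- priors$df
  # Residual covariances between breed-traits never observed on the same
  # individual are not likelihood-identified; with data augmentation their
  # chain is a slow random walk that can pin near +-1 and contaminate the
  # block genetic correlations. In that missing-by-design case R_0 is
  # constrained diagonal, under which the missing cells marginalize out
  # exactly: the sampler then updates from observed cells only (no
  # imputation pseudo-data, much faster mixing). Fully (jointly) observed
  # layouts keep the full inverse-Wishart update with data augmentation.
  pairs_obs <- crossprod(obs)
  marginal <- p > 1L && any(pairs_obs[upper.tri(pairs_obs)] == 0)

  # initial state
  Bcoef <- matrix(0, q, p)
  mu0 <- colMeans(Y, na.rm = TRUE)
  mu0[!is.finite(mu0)] <- 0
  Bcoef[1, ] <- mu0
  A <- matrix(0, m, p, dimnames = list(panel$map$id, breeds))
  # start G_i at (df-1) B_i, i.e. h2 P / (s * sum 2pq): the implied total
  # genetic variance then matches the heritability prior from cycle one,
  # which shortens the burn-in the variance components need to climb
  G <- array(0, c(p, p, s))
  for (i in seq_len(s)) G[, , i] <- (df - 1) * priors$B[[i]]
  R0 <- (1 - priors$h2) * priors$P
  E <- Y - X %*% Bcoef
  E[!obs] <- 0

  ord <- if (is.null(block_order)) seq_len(s) else as.integer(block_order)
  stopifnot(length(ord) == s, setequal(ord, seq_len(s)))
  if (marginal) {
    Obs <- matrix(as.double(obs), n, p)
    Xtx <- crossprod(M * M, Obs)          # per-trait SNP sums of squares
    obs_rows <- lapply(seq_len(p), function(l) which(obs[, l]))
    n_obs <- vapply(obs_rows, length, 0L)
  }
  n_store <- (config$n_iter - config$burn_in) %/% config$thin
  acc <- list(b = 0, A = 0, G = 0, R0 = 0, g = 0, g2 = 0)
  draws <- if (keep_draws)
    list(G = array(NA_real_, c(p, p, s, n_store)),
         R0 = array(NA_real_, c(p, p, n_store)))
  else NULL
  stored <- 0L

  for (it in seq_len(config$n_iter)) {
    if (marginal) {
      for (l in seq_len(p)) {
        rl <- obs_rows[[l]]
        if (n_obs[l] <= q) next
        Xl <- X[rl, , drop = FALSE]
        Ystar_l <- Xl %*% Bcoef[, l] + E[rl, l]
        Bcoef[, l] <- sample_fixed_effects(Ystar_l, Xl,
                                           R0[l, l, drop = FALSE])
        E[rl, l] <- Ystar_l - Xl %*% Bcoef[, l]
      }
      res <- gibbs_effects_masked_cpp(M, A, E, G[, , ord, drop = FALSE],
                                      diag(R0), blockmap$first[ord],
                                      blockmap$last[ord], Obs, Xtx)
    } else {
      E <- impute_missing_phenotypes(E, R0, obs)
      Ystar <- X %*% Bcoef + E
      Bcoef <- sample_fixed_effects(Ystar, X, R0)
      E <- Ystar - X %*% Bcoef
      res <- gibbs_effects_cpp(M, A, E, G[, , ord, drop = FALSE], R0,
                               blockmap$first[ord], blockmap$last[ord])
    }
    A <- res$A; E <- res$E
    for (i in seq_len(s))
      G[, , i] <- sample_block_covariance(
        A[blockmap$first[i]:blockmap$last[i], , drop = FALSE],
        priors$B[[i]], df)
    R0 <- if (marginal) {
      diag(vapply(seq_len(p), function(l)
        drop(rinvwishart(df + n_obs[l],
                         sum(E[obs_rows[[l]], l]^2) +
                           priors$R_p[l, l, drop = FALSE])),
        0), p, p)
    } else sample_residual_covariance(E, priors$R_p, df)
    if (!all(is.finite(R0)) || !all(is.finite(E)))
      stop("sampler diverged (non-finite state) at iteration ", it)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      stored <- stored + 1L
      g <- M %*% A
      acc$b <- acc$b + Bcoef
      acc$A <- acc$A + A
      acc$G <- acc$G + G
      acc$R0 <- acc$R0 + R0
      acc$g <- acc$g + g
      acc$g2 <- acc$g2 + g * g
      if (keep_draws) {
        draws$G[, , , stored] <- G
        draws$R0[, , stored] <- R0
      }
    }
    if (verbose && it %% 1000L == 0L)
      message("cycle ", it, "/", config$n_iter)
  }
  if (stored == 0L) stop("no samples stored; check n_iter/burn_in/thin")

  Gm <- acc$G / stored
  r_block <- array(NA_real_, c(p, p, s))
  for (i in seq_len(s)) {
    Gi <- matrix(Gm[, , i], p, p)
    d <- sqrt(diag(Gi))
    r_block[, , i] <- Gi / tcrossprod(d)
  }
  gebv <- acc$g / stored
  gvar <- (acc$g2 - stored * gebv^2) / max(stored - 1L, 1L)
  gebv_sd <- sqrt(pmax(gvar, 0))
  dimnames(gebv) <- dimnames(gebv_sd) <- list(pheno$ids, breeds)
  structure(list(b = acc$b / stored, effects = acc$A / stored,
                 G = Gm, R0 = acc$R0 / stored, r_block = r_block,
                 gebv = gebv, gebv_sd = gebv_sd, n_stored = stored,
                 breeds = breeds, blockmap = blockmap, config = config,
                 priors = priors, draws = draws),
            class = "mbgp_post")
}

#' @export
print.mbgp_post <- function(x, ...) {
  cat("mbgp_post: blockwise multitrait BayesA fit\n")
  cat("  breeds:", paste(x$breeds, collapse = ", "),
      " blocks:", dim(x$G)[3], " stored samples:", x$n_stored, "\n")
  cat("  posterior mean residual covariance:\n")
  print(round(x$R0, 5))
  invisible(x)
}

#' Genomic estimated breeding values from posterior-mean effects
#'
#' Multiplies a dosage panel with posterior-mean marker effects. This is how
#' individuals absent from the training run are scored; for individuals in
#' the run itself, prefer the `gebv` element of the fit (accumulated across
#' stored samples; the two differ only by Monte-Carlo error).
#'
#' @param effects m x p matrix of posterior-mean SNP effects with SNP ids as
#'   row names (the `effects` element of an `mbgp_post`).
#' @param panel a `genotype_panel` with the same SNP set.
#' @return n x p matrix of GEBVs, one column per breed-trait.
#' @export
compute_gebv <- function(effects, panel) {
  effects <- as.matrix(effects)
  if (ncol(panel$geno) != nrow(effects))
    stop("SNP set mismatch between panel and effects")
  if (!is.null(rownames(effects)) &&
      !identical(rownames(effects), colnames(panel$geno)))
    stop("SNP ids of panel and effects disagree")
  out <- panel$geno %*% effects
  rownames(out) <- panel$fam$id
  out
}
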