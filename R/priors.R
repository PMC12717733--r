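#' Prior specification for the blockwise multitrait BayesA model
#'
#' Builds the informative inverse-Wishart hyperparameters from the phenotypes
#' and the merged-panel allele frequencies. With p breed-traits the degrees
#' of freedom are `df = 4 + p`. The block scale matrices split a prior
#' heritability `h2` of the phenotypic variance evenly across the s blocks,
#' scaled by each block's expected marker variance:
#'
#' \deqn{B_i = \tilde h^2 P / [s (df-1) \sum_{j \in i} 2 p_j (1-p_j)]}
#' \deqn{R_p = (1-\tilde h^2) P / (df-1)}
#'
#' where `P` is the diagonal matrix of per-breed phenotypic variances and
#' `p_j` the allele frequency of SNP j across breeds. Prior covariances
#' between breeds are zero (`P` diagonal).
#'
#' @param pheno a `pheno_table`.
#' @param panel the merged `genotype_panel`.
#' @param blockmap a `block_map` tiling the panel.
#' @param h2 prior heritability (default 0.5, moderately informative).
#' @return An object of class `prior_spec`: list with `p`, `df`, `h2`, `P`,
#'   `B` (list of per-block scale matrices), `R_p`, `s`.
#' @export
build_priors <- function(pheno, panel, blockmap, h2 = 0.5) {
  breeds <- pheno$breeds
  p <- length(breeds)
  vars <- apply(pheno$Y, 2, stats::var, na.rm = TRUE)
  if (anyNA(vars) || any(vars <= 0))
    stop("zero phenotypic variance in breed(s): ",
         paste(breeds[is.na(vars) | vars <= 0], collapse = ", "))
  df <- 4 + p
  P <- diag(vars, p)
  dimnames(P) <- list(breeds, breeds)
  s <- nrow(blockmap)
  af <- allele_freq(panel)
  het <- 2 * af * (1 - af)
  B <- vector("list", s)
  for (i in seq_len(s)) {
    ss <- sum(het[blockmap$first[i]:blockmap$last[i]])
    if (ss <= 0)
      stop("block ", i, " is entirely monomorphic; prior scale undefined")
    B[[i]] <- h2 * P / (s * (df - 1) * ss)
  }
  R_p <- (1 - h2) * P / (df - 1)
  structure(list(p = p, df = df, h2 = h2, P = P, B = B, R_p = R_p, s = s,
                 breeds = breeds),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec: p =", x$p, " df =", x$df, " h2 =", x$h2,
      " blocks =", x$s, "\n")
  cat("  phenotypic variances:",
      paste(sprintf("%s = %.4g", x$breeds, diag(x$P)), collapse = ", "), "\n")
  invisible(x)
}

#' MCMC settings
#'
#' @param n_iter total Gibbs cycles (default 30000).
#' @param burn_in cycles discarded as burn-in (default 20000).
#' @param thin thinning interval for stored samples (default 10).
#' @param seed optional RNG seed set at the start of the run.
#' @return An object of class `mcmc_config`. The number of stored samples is
#'   `(n_iter - burn_in) / thin`.
#' @export
mcmc_config <- function(n_iter = 30000L, burn_in = 20000L, thin = 10L,
                        seed = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1L, n_iter >= 1L, burn_in >= 0L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_config")
}
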