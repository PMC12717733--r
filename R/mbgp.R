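#' Fit a multibreed genomic prediction model
#'
#' Single front-end for the four model families: the blockwise multitrait
#' BayesA model on LD blocks (`"mbbayes_ld"`) or fixed-size blocks
#' (`"mbbayes_fix"`), single-trait GBLUP pooling all breeds (`"stgblup"`),
#' and multitrait GBLUP treating the trait in each breed as distinct
#' correlated traits (`"mtgblup"`).
#'
#' @param pheno a `pheno_table` (see [phenotype_table()]); mask validation
#'   candidates with [mask_phenotypes()] or leave them without records.
#' @param panel the merged `genotype_panel`.
#' @param method model family.
#' @param blocks optional `block_map` for the Bayesian models; by default
#'   computed from the reference individuals (those with an observed
#'   phenotype) with [partition_genome()].
#' @param mcmc an `mcmc_config` for the Bayesian models.
#' @param h2_prior prior heritability for the Bayesian models.
#' @param n_win,spar,block_size partition parameters.
#' @return An object of class `mbgp_fit` with methods [print()],
#'   [summary()], [coef()] (marker effects or variance components),
#'   [predict()] (GEBVs, optionally for a new panel), [fitted()] and
#'   [residuals()].
#' @examples
#' cfg <- two_breed_config(n_ind = c(80, 40), snps_per_chr = 60, n_chr = 2,
#'                         hist_generations = 30, seed = 7)
#' cfg$arch <- arch_config(n_uncorr = 5, n_corr = 2, qtl_per_corr = 3,
#'                         r_g_mean = 0.8)
#' d <- simulate_dataset(cfg)
#' fit <- mbgp(d$pheno, d$panel, method = "mbbayes_ld",
#'             mcmc = mcmc_config(300, 100, 2, seed = 1))
#' fit
#' head(predict(fit))
#' @export
mbgp <- function(pheno, panel, method = c("mbbayes_ld", "mbbayes_fix",
                                          "stgblup", "mtgblup"),
                 blocks = NULL, mcmc = mcmc_config(), h2_prior = 0.5,
                 n_win = 50L, spar = 0.2, block_size = 100L) {
  method <- match.arg(method)
  breeds <- pheno$breeds
  inner <- switch(
    method,
    mbbayes_ld = ,
    mbbayes_fix = {
      if (is.null(blocks)) {
        ref <- which(rowSums(!is.na(pheno$Y)) > 0)
        ref_panel <- if (length(ref) < nrow(panel$geno))
          subset_panel(panel, samples = ref) else panel
        blocks <- if (method == "mbbayes_ld")
          partition_genome(ref_panel, "ld", n_win = n_win, spar = spar)
        else partition_genome(panel, "fixed", block_size = block_size)
      }
      priors <- build_priors(pheno, panel, blocks, h2 = h2_prior)
      run_gibbs(pheno, panel, blocks, priors = priors, config = mcmc)
    },
    stgblup = {
      grm <- build_grm(panel)
      X <- cbind(pheno$X, stats::model.matrix(
        ~ breed - 1, data.frame(breed = panel$fam$breed)))
      X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
      y <- pheno$Y[cbind(seq_len(nrow(pheno$Y)),
                         match(panel$fam$breed, breeds))]
      names(y) <- pheno$ids
      fit_stgblup(y, X, grm)
    },
    mtgblup = fit_mtgblup(pheno, build_grm(panel)))
  structure(list(method = method, fit = inner, breeds = breeds,
                 pheno = pheno, panel_dim = dim(panel$geno),
                 snp_ids = panel$map$id,
                 breed_of = panel$fam$breed, ids = pheno$ids),
            class = "mbgp_fit")
}

# n x p GEBV matrix for any method
.gebv_matrix <- function(object) {
  f <- object$fit
  if (inherits(f, "mbgp_post")) return(f$gebv)
  if (f$method == "stgblup")
    return(matrix(f$gebv, ncol = length(object$breeds),
                  nrow = length(f$gebv),
                  dimnames = list(object$ids, object$breeds)))
  f$gebv
}

#' @export
print.mbgp_fit <- function(x, ...) {
  cat("mbgp_fit:", x$method, "on", x$panel_dim[1], "individuals x",
      x$panel_dim[2], "SNPs;", length(x$breeds), "breed(s)\n")
  print(x$fit)
  invisible(x)
}

#' @export
summary.mbgp_fit <- function(object, ...) {
  g <- .gebv_matrix(object)
  own <- g[cbind(seq_len(nrow(g)), match(object$breed_of, object$breeds))]
  out <- list(method = object$method, breeds = object$breeds,
              gebv_summary = do.call(rbind, lapply(
                split(own, object$breed_of), summary)))
  if (inherits(object$fit, "mbgp_post")) {
    rb <- object$fit$r_block
    if (dim(rb)[1] >= 2)
      out$block_correlations <- summary(rb[1, 2, ])
    out$R0 <- object$fit$R0
  } else if (object$fit$method == "mtgblup") {
    out$G0 <- object$fit$G0
    out$r_g <- object$fit$r_g
  } else {
    out$h2 <- object$fit$h2
  }
  class(out) <- "summary.mbgp_fit"
  out
}

#' @export
print.summary.mbgp_fit <- function(x, ...) {
  cat("Multibreed genomic prediction fit (", x$method, ")\n\n", sep = "")
  cat("Own-breed GEBV distribution:\n")
  print(x$gebv_summary)
  if (!is.null(x$block_correlations)) {
    cat("\nPer-block genetic correlation (breeds ", x$breeds[1], "/",
        x$breeds[2], "):\n", sep = "")
    print(x$block_correlations)
  }
  if (!is.null(x$r_g)) {
    cat("\nGenetic correlation matrix:\n"); print(round(x$r_g, 3))
  }
  if (!is.null(x$h2)) cat("\nEstimated h2:", round(x$h2, 3), "\n")
  invisible(x)
}

#' @export
coef.mbgp_fit <- function(object, ...) {
  f <- object$fit
  if (inherits(f, "mbgp_post")) return(f$effects)
  if (f$method == "mtgblup") return(f$G0)
  c(sigma2_a = f$sigma2_a, sigma2_e = f$sigma2_e)
}

#' @export
predict.mbgp_fit <- function(object, panel = NULL, ...) {
  if (is.null(panel)) return(.gebv_matrix(object))
  f <- object$fit
  if (inherits(f, "mbgp_post")) return(compute_gebv(f$effects, panel))
  stop("predict() on a new panel requires a Bayesian (marker-effect) fit")
}

#' @export
fitted.mbgp_fit <- function(object, ...) {
  g <- .gebv_matrix(object)
  g[cbind(seq_len(nrow(g)), match(object$breed_of, object$breeds))]
}

#' @export
residuals.mbgp_fit <- function(object, ...) {
  y <- object$pheno$Y[cbind(seq_len(nrow(object$pheno$Y)),
                            match(object$breed_of, object$breeds))]
  y - fitted(object)
}

#' Tidy GEBV table from a fit
#'
#' @param object an `mbgp_fit` or `mbgp_post`.
#' @return data.frame with columns `id`, `breed`, `gebv` and (Bayesian
#'   fits) `gebv_sd`, one row per individual x breed-trait.
#' @export
gebv_table <- function(object) {
  if (inherits(object, "mbgp_fit")) {
    g <- .gebv_matrix(object)
    sd <- if (inherits(object$fit, "mbgp_post")) object$fit$gebv_sd else NULL
  } else {
    g <- object$gebv; sd <- object$gebv_sd
  }
  out <- data.frame(id = rep(rownames(g), ncol(g)),
                    breed = rep(colnames(g), each = nrow(g)),
                    gebv = as.vector(g), stringsAsFactors = FALSE)
  if (!is.null(sd)) out$gebv_sd <- as.vector(sd)
  out
}
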