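#' Stratified cross-validation plan
#'
#' Folds are drawn within each breed so fold sizes differ by at most one
#' per breed, independently for each repeat; the same plan (hence the same
#' validation subsets) is applied to every model compared.
#'
#' @param pheno a `pheno_table` (breed labels come from its panel order).
#' @param breeds_of optional character vector of breed per individual;
#'   defaults to the breed-trait with the observed cell.
#' @param k folds (default 5).
#' @param repeats plan repeats (5 for simulated data, 10 for real-style).
#' @param seed RNG seed for the assignment.
#' @return An object of class `cv_plan`: `folds` is an n x repeats integer
#'   matrix of fold ids (NA for individuals with no observed phenotype,
#'   which stay in the reference).
#' @export
make_cv_plan <- function(pheno, k = 5L, repeats = 5L, seed = 1L,
                         breeds_of = NULL) {
  if (is.null(breeds_of)) {
    breeds_of <- rep(NA_character_, nrow(pheno$Y))
    oc <- which(!is.na(pheno$Y), arr.ind = TRUE)
    breeds_of[oc[, 1]] <- pheno$breeds[oc[, 2]]
  }
  set.seed(seed)
  n <- length(pheno$ids)
  folds <- matrix(NA_integer_, n, repeats)
  for (br in stats::na.omit(unique(breeds_of))) {
    idx <- which(breeds_of == br)
    if (length(idx) < k)
      stop("breed ", br, " has fewer than k = ", k, " individuals")
    for (r in seq_len(repeats))
      folds[sample(idx), r] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 folds = folds, ids = pheno$ids, breeds_of = breeds_of,
                 seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("cv_plan:", x$k, "folds x", x$repeats, "repeats over",
      sum(!is.na(x$folds[, 1])), "phenotyped individuals\n")
  invisible(x)
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBVs and the scoring target (true breeding
#' values in simulations, pre-adjusted phenotypes otherwise). Undefined
#' (zero-variance) cases are reported as `NA`.
#'
#' @param gebv,target aligned numeric vectors, length >= 3.
#' @return correlation, or `NA_real_` if either vector has zero variance.
#' @export
accuracy <- function(gebv, target) {
  stopifnot(length(gebv) == length(target), length(gebv) >= 3L)
  if (stats::sd(gebv) == 0 || stats::sd(target) == 0) return(NA_real_)
  stats::cor(gebv, target)
}

#' Dispersion bias (unbiasedness)
#'
#' Ordinary least-squares slope of the target on the GEBVs:
#' `cov(target, gebv) / var(gebv)`. 1 is unbiased; values below 1 indicate
#' inflated GEBV spread.
#'
#' @inheritParams accuracy
#' @return regression slope, or `NA_real_` if the GEBVs have zero variance.
#' @export
unbiasedness <- function(gebv, target) {
  stopifnot(length(gebv) == length(target), length(gebv) >= 3L)
  vg <- stats::var(gebv)
  if (vg == 0) return(NA_real_)
  stats::cov(target, gebv) / vg
}

#' Paired t-test between two models' per-cell scores
#'
#' Two-sided paired t-test over cells paired by (repeat, fold). Degenerate
#' cases follow fixed conventions: all differences zero gives p = 1; a
#' constant non-zero difference gives p = 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b equal-length numeric vectors of per-cell scores.
#' @return two-sided p-value.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("need at least 2 paired cells")
  d <- a - b
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(structure(0, degenerate = TRUE))
  stats::t.test(a, b, paired = TRUE)$p.value
}

# squared dosage correlations for all pairs within window_bp, one chromosome
.r2_pairs <- function(G, pos, window_bp) {
  m <- ncol(G)
  sds <- apply(G, 2, stats::sd)
  Z <- matrix(0, nrow(G), m)
  ok <- sds > 0
  Z[, ok] <- scale(G[, ok, drop = FALSE])
  out_i <- integer(0); out_j <- integer(0); out_r2 <- numeric(0)
  for (d in seq_len(m - 1L)) {
    i <- seq_len(m - d)
    within <- pos[i + d] - pos[i] <= window_bp
    if (!any(within)) break
    i <- i[within]
    r2 <- (colSums(Z[, i, drop = FALSE] * Z[, i + d, drop = FALSE]) /
             (nrow(G) - 1))^2
    keep <- ok[i] & ok[i + d]
    out_i <- c(out_i, i[keep]); out_j <- c(out_j, (i + d)[keep])
    out_r2 <- c(out_r2, r2[keep])
  }
  data.frame(i = out_i, j = out_j, r2 = out_r2)
}

#' Consistency of LD patterns between two populations
#'
#' Within each population, r-squared (squared dosage correlation) is
#' computed for every SNP pair closer than `window_bp`; the statistic is
#' the Pearson correlation of the paired r-squared values across the two
#' populations over their shared segregating SNPs. With the default 10-Mbp
#' window this is the R10Mbp measure of LD-pattern conservation.
#'
#' @param panelA,panelB `genotype_panel`s sharing SNP ids.
#' @param window_bp maximum pair distance in bp (default 1e7).
#' @return Pearson correlation of paired r-squared values.
#' @export
ld_consistency <- function(panelA, panelB, window_bp = 1e7) {
  shared <- intersect(panelA$map$id, panelB$map$id)
  ia <- match(shared, panelA$map$id); ib <- match(shared, panelB$map$id)
  segA <- apply(panelA$geno[, ia, drop = FALSE], 2, stats::sd) > 0
  segB <- apply(panelB$geno[, ib, drop = FALSE], 2, stats::sd) > 0
  keep <- segA & segB
  ia <- ia[keep]; ib <- ib[keep]
  if (!length(ia)) stop("no shared segregating SNPs")
  r2a <- r2b <- numeric(0)
  for (ch in unique(panelA$map$chrom[ia])) {
    ca <- ia[panelA$map$chrom[ia] == ch]
    cb <- match(panelA$map$id[ca], panelB$map$id)
    pa <- .r2_pairs(panelA$geno[, ca, drop = FALSE],
                    panelA$map$pos[ca], window_bp)
    pb <- .r2_pairs(panelB$geno[, cb, drop = FALSE],
                    panelB$map$pos[cb], window_bp)
    key_a <- paste(pa$i, pa$j); key_b <- paste(pb$i, pb$j)
    common <- intersect(key_a, key_b)
    r2a <- c(r2a, pa$r2[match(common, key_a)])
    r2b <- c(r2b, pb$r2[match(common, key_b)])
  }
  if (length(r2a) < 2L) stop("no qualifying SNP pairs within the window")
  stats::cor(r2a, r2b)
}

#' Allele-frequency correlation between two populations
#'
#' Pearson correlation of minor-allele frequencies (minor defined on the
#' merged pair) over SNPs segregating in both populations.
#'
#' @param panelA,panelB `genotype_panel`s sharing SNP ids.
#' @return Pearson correlation.
#' @export
allele_freq_corr <- function(panelA, panelB) {
  shared <- intersect(panelA$map$id, panelB$map$id)
  ia <- match(shared, panelA$map$id); ib <- match(shared, panelB$map$id)
  fa <- colMeans(panelA$geno[, ia, drop = FALSE]) / 2
  fb <- colMeans(panelB$geno[, ib, drop = FALSE]) / 2
  na <- nrow(panelA$geno); nb <- nrow(panelB$geno)
  fm <- (na * fa + nb * fb) / (na + nb)
  seg <- fa > 0 & fa < 1 & fb > 0 & fb < 1
  if (sum(seg) < 3L) stop("fewer than 3 jointly segregating SNPs")
  flip <- fm > 0.5
  fa[flip] <- 1 - fa[flip]; fb[flip] <- 1 - fb[flip]
  stats::cor(fa[seg], fb[seg])
}

#' Cross-validated model comparison
#'
#' For every (repeat, fold) of the plan, masks the validation individuals'
#' phenotypes, fits each requested model on the identical reference, scores
#' the validation individuals of each breed against the target (TBV when a
#' truth set is available, pre-adjusted phenotypes otherwise), and
#' aggregates accuracy and unbiasedness with paired t-tests between models.
#'
#' @param data list with `panel`, `pheno`, and optionally `truth` (as from
#'   [simulate_dataset()]).
#' @param models character subset of `c("mbbayes_ld", "mbbayes_fix",
#'   "stgblup", "mtgblup")`.
#' @param cvplan a `cv_plan`; defaults to 5 folds x 1 repeat, seed 1.
#' @param mcmc `mcmc_config` for the Bayesian models.
#' @param n_win,spar,block_size partition parameters.
#' @param folds optionally restrict scoring to a subset of fold ids.
#' @param verbose print progress.
#' @return An object of class `eval_result`: `cells` (per model, breed,
#'   repeat, fold scores), `summary` (means and SEs), `ttests` (pairwise
#'   paired t-tests on accuracy per breed).
#' @export
run_benchmark <- function(data, models = c("mbbayes_ld", "stgblup"),
                          cvplan = NULL, mcmc = mcmc_config(3000L, 1000L, 5L),
                          n_win = 50L, spar = 0.2, block_size = 100L,
                          folds = NULL, verbose = FALSE) {
  models <- match.arg(models, c("mbbayes_ld", "mbbayes_fix", "stgblup",
                                "mtgblup"), several.ok = TRUE)
  panel <- data$panel; pheno <- data$pheno
  if (is.null(cvplan))
    cvplan <- make_cv_plan(pheno, k = 5L, repeats = 1L, seed = 1L)
  breeds <- pheno$breeds
  # scoring target per individual
  if (!is.null(data$truth)) {
    target_of <- data$truth$tbv_own
  } else {
    # pre-adjusted phenotype: observed value minus fixed-effect estimates
    # from a single-trait fit on the full data, once per trait
    grm_full <- build_grm(panel)
    Xst <- cbind(pheno$X,
                 stats::model.matrix(~ breed - 1,
                                     data.frame(breed = panel$fam$breed)))
    Xst <- Xst[, qr(Xst)$pivot[seq_len(qr(Xst)$rank)], drop = FALSE]
    yall <- pheno$Y[cbind(seq_len(nrow(pheno$Y)),
                          match(panel$fam$breed, breeds))]
    st <- fit_stgblup(yall, Xst, grm_full)
    target_of <- yall - drop(Xst %*% st$b)
  }
  cells <- list()
  fold_set <- if (is.null(folds)) seq_len(cvplan$k) else folds
  for (r in seq_len(cvplan$repeats)) for (f in fold_set) {
    val <- which(cvplan$folds[, r] == f)
    ref <- setdiff(which(!is.na(cvplan$folds[, r])), val)
    ph_m <- mask_phenotypes(pheno, pheno$ids[val])
    ref_panel <- subset_panel(panel, samples = ref)
    bm_ld <- bm_fix <- NULL
    fits <- list()
    for (mod in models) {
      if (verbose) message("repeat ", r, " fold ", f, ": ", mod)
      gebv_mat <- switch(
        mod,
        mbbayes_ld = {
          if (is.null(bm_ld))
            bm_ld <- partition_genome(ref_panel, "ld", n_win = n_win,
                                      spar = spar)
          run_gibbs(ph_m, panel, bm_ld, config = mcmc)$gebv
        },
        mbbayes_fix = {
          if (is.null(bm_fix))
            bm_fix <- partition_genome(panel, "fixed",
                                       block_size = block_size)
          run_gibbs(ph_m, panel, bm_fix, config = mcmc)$gebv
        },
        stgblup = {
          g <- build_grm(panel)
          Xst <- cbind(ph_m$X, stats::model.matrix(
            ~ breed - 1, data.frame(breed = panel$fam$breed)))
          Xst <- Xst[, qr(Xst)$pivot[seq_len(qr(Xst)$rank)], drop = FALSE]
          ym <- ph_m$Y[cbind(seq_len(nrow(ph_m$Y)),
                             match(panel$fam$breed, breeds))]
          fit <- fit_stgblup(ym, Xst, g)
          matrix(fit$gebv, ncol = length(breeds),
                 nrow = length(fit$gebv),
                 dimnames = list(pheno$ids, breeds))
        },
        mtgblup = fit_mtgblup(ph_m, build_grm(panel))$gebv)
      for (br in breeds) {
        vb <- val[panel$fam$breed[val] == br]
        if (length(vb) < 3L) next
        gv <- gebv_mat[vb, br]
        tg <- target_of[vb]
        cells[[length(cells) + 1L]] <- data.frame(
          model = mod, breed = br, repeat_ = r, fold = f,
          accuracy = accuracy(gv, tg), slope = unbiasedness(gv, tg),
          n_val = length(vb), stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  agg <- do.call(rbind, lapply(split(
    cells, list(cells$model, cells$breed), drop = TRUE), function(d)
      data.frame(model = d$model[1], breed = d$breed[1],
                 accuracy = mean(d$accuracy, na.rm = TRUE),
                 accuracy_se = stats::sd(d$accuracy, na.rm = TRUE) /
                   sqrt(sum(!is.na(d$accuracy))),
                 slope = mean(d$slope, na.rm = TRUE),
                 slope_se = stats::sd(d$slope, na.rm = TRUE) /
                   sqrt(sum(!is.na(d$slope))),
                 n_cells = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  tt <- list()
  if (length(models) > 1L) {
    for (br in breeds) for (i in seq_along(models)[-length(models)])
      for (j in (i + 1):length(models)) {
        a <- cells[cells$model == models[i] & cells$breed == br, ]
        b <- cells[cells$model == models[j] & cells$breed == br, ]
        key <- paste(a$repeat_, a$fold)
        b <- b[match(key, paste(b$repeat_, b$fold)), ]
        if (nrow(a) >= 2L && all(!is.na(b$accuracy)) &&
            all(!is.na(a$accuracy)))
          tt[[length(tt) + 1L]] <- data.frame(
            breed = br, model_a = models[i], model_b = models[j],
            p_value = as.numeric(paired_ttest(a$accuracy, b$accuracy)),
            stringsAsFactors = FALSE)
      }
  }
  structure(list(cells = cells, summary = agg,
                 ttests = if (length(tt)) do.call(rbind, tt) else NULL,
                 models = models),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("eval_result over", nrow(x$cells), "model x breed x fold cells\n\n")
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$ttests)) {
    cat("\npaired t-tests (accuracy):\n")
    print(x$ttests, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
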