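# Full conditional samplers for the blockwise multitrait BayesA model.
# All covariance draws go through safe_chol(): symmetrize, one shot of
# trace-scaled jitter, then fail loudly rather than continue silently.

safe_chol <- function(S, what = "matrix") {
  S <- (S + t(S)) / 2
  r <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(r)) {
    S <- S + diag(1e-10 * sum(diag(S)) + 1e-300, nrow(S))
    r <- tryCatch(chol(S),
                  error = function(e) stop(what, " is not positive definite"))
  }
  r
}

#' Inverse-Wishart draw
#'
#' Draws from IW(nu, S) in the parameterization with mean `S / (nu - p - 1)`
#' for `nu > p + 1`, via [stats::rWishart()] on the inverted scale.
#'
#' @param nu degrees of freedom (> p - 1).
#' @param S p x p positive-definite scale matrix.
#' @return A p x p positive-definite draw.
#' @export
rinvwishart <- function(nu, S) {
  U <- safe_chol(S, "inverse-Wishart scale")
  Sinv <- chol2inv(U)
  W <- stats::rWishart(1, nu, (Sinv + t(Sinv)) / 2)[, , 1]
  out <- chol2inv(safe_chol(W, "Wishart draw"))
  (out + t(out)) / 2
}

#' Draw fixed-effect coefficients
#'
#' Full conditional of the fixed-effect coefficient matrix given the
#' marker-corrected phenotypes `Ystar = Y - sum_i M_i A_i` and the current
#' residual covariance. With the design shared across breed-traits and
#' residuals `N(0, I_n (x) R0)`, the conditional is matrix-normal with mean
#' the GLS solution and covariance `R0 (x) (X'X)^{-1}`.
#'
#' @param Ystar n x p marker-corrected phenotype matrix (complete, i.e.
#'   after imputation of structurally missing cells).
#' @param X n x q fixed-effect design (intercept first column); coefficients
#'   are estimated per breed-trait.
#' @param R0 current p x p residual covariance.
#' @return q x p coefficient matrix draw.
#' @export
sample_fixed_effects <- function(Ystar, X, R0) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    aliased <- colnames(X)[-seq_len(qr_$rank)]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  XtX <- crossprod(X)
  Bhat <- solve(XtX, crossprod(X, Ystar))
  L <- t(safe_chol(chol2inv(safe_chol(XtX, "X'X")), "(X'X)^-1"))
  Z <- matrix(stats::rnorm(ncol(X) * ncol(Ystar)), ncol(X), ncol(Ystar))
  Bhat + L %*% Z %*% safe_chol(R0, "R0")
}

#' Draw marker effects for one block
#'
#' Updates the p-variate effects of every SNP in a block, one SNP at a time,
#' from the conditional normal with prior covariance the current block
#' genetic covariance `G_i`, keeping the residual matrix in sync so the
#' corrected phenotype never needs re-materializing. The per-SNP conditional
#' has precision `(m_j' m_j) R0^{-1} + G_i^{-1}`.
#'
#' @param M n x m_i dosage matrix of the block's SNPs.
#' @param A m_i x p current effect matrix for the block.
#' @param E n x p current residual matrix (updated in step with the draws).
#' @param G_i current p x p block genetic covariance.
#' @param R0 current p x p residual covariance.
#' @return list with updated `A` and `E`.
#' @export
sample_block_effects <- function(M, A, E, G_i, R0) {
  M <- as.matrix(M); A <- as.matrix(A); E <- as.matrix(E)
  G_i <- as.matrix(G_i); R0 <- as.matrix(R0)
  res <- gibbs_effects_cpp(M, A, E, array(G_i, c(nrow(G_i), ncol(G_i), 1L)),
                           R0, 1L, ncol(M))
  list(A = res$A, E = res$E)
}

#' Draw a block genetic covariance matrix
#'
#' Full conditional `IW(df + m_i, sum_j a_ij a_ij' + B_i)`.
#'
#' @param A m_i x p current effect matrix of the block.
#' @param B_i p x p prior scale matrix of the block.
#' @param df prior degrees of freedom (4 + p).
#' @return p x p covariance draw.
#' @export
sample_block_covariance <- function(A, B_i, df) {
  A <- as.matrix(A)
  rinvwishart(df + nrow(A), crossprod(A) + B_i)
}

#' Draw the residual covariance matrix
#'
#' Full conditional `IW(df + n, sum_i e_i e_i' + R_p)` over the complete
#' (imputation-augmented) residuals.
#'
#' @param E n x p residual matrix.
#' @param R_p p x p residual prior scale.
#' @param df prior degrees of freedom (4 + p).
#' @return p x p covariance draw.
#' @export
sample_residual_covariance <- function(E, R_p, df) {
  E <- as.matrix(E)
  rinvwishart(df + nrow(E), crossprod(E) + R_p)
}

#' Impute structurally missing residuals
#'
#' Data-augmentation step: for each individual, the residuals of the
#' unobserved breed-traits are redrawn from the conditional normal of the
#' missing components given the observed ones under `e_i ~ N(0, R0)`. The
#' imputed phenotype is then fixed + genetic + drawn residual by
#' construction. Rows observed for every trait are left unchanged; rows with
#' no observed trait are drawn from the full `N(0, R0)`.
#'
#' @param E n x p residual matrix (missing cells hold the previous draws).
#' @param R0 current p x p residual covariance.
#' @param obs n x p logical matrix, `TRUE` where the breed-trait is observed.
#' @return The residual matrix with missing cells redrawn.
#' @export
impute_missing_phenotypes <- function(E, R0, obs) {
  E <- as.matrix(E)
  p <- ncol(E)
  if (!any(!obs)) return(E)
  pat <- obs %*% (2^(seq_len(p) - 1))
  for (pt in unique(pat[rowSums(obs) < p])) {
    rows <- which(pat == pt)
    o <- which(obs[rows[1], ])
    ms <- which(!obs[rows[1], ])
    if (length(o) == 0L) {
      Z <- matrix(stats::rnorm(length(rows) * p), length(rows), p)
      E[rows, ] <- Z %*% safe_chol(R0, "R0")
      next
    }
    Roo <- R0[o, o, drop = FALSE]
    Rmo <- R0[ms, o, drop = FALSE]
    K <- Rmo %*% chol2inv(safe_chol(Roo, "R0[obs,obs]"))
    cvar <- R0[ms, ms, drop = FALSE] - K %*% t(Rmo)
    mu <- E[rows, o, drop = FALSE] %*% t(K)
    Z <- matrix(stats::rnorm(length(rows) * length(ms)),
                length(rows), length(ms))
    E[rows, ms] <- mu + Z %*% safe_chol(cvar, "conditional residual covariance")
  }
  E
}
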