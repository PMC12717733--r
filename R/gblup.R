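#' Single-trait GBLUP with spectral REML
#'
#' Treats all breeds in the reference as one population with a shared
#' genetic background: `y = Xb + g + e`, `g ~ N(0, sigma2_a G)`. The single
#' random effect permits exact REML through the eigendecomposition of the
#' GRM over the phenotyped individuals; the variance ratio is then found by
#' one-dimensional optimization of the restricted likelihood. Individuals
#' with missing phenotype (validation candidates) receive GEBVs through
#' their GRM rows.
#'
#' @param y named numeric vector over all panel individuals; `NA` marks
#'   individuals without (or with withheld) phenotype.
#' @param X fixed-effect design over all individuals (intercept, and e.g.
#'   breed indicators and sex). Must be full rank on the observed subset.
#' @param grm a `grm` covering all individuals, in the order of `y`.
#' @return An object of class `gblup_fit` with elements `sigma2_a`,
#'   `sigma2_e`, `h2`, `loglik`, `b`, and `gebv` (named, all individuals).
#' @export
fit_stgblup <- function(y, X, grm) {
  X <- as.matrix(X)
  o <- which(!is.na(y))
  if (length(o) < ncol(X) + 2L) stop("too few phenotyped individuals")
  yo <- y[o]
  Xo <- X[o, , drop = FALSE]
  qr_ <- qr(Xo)
  if (qr_$rank < ncol(Xo))
    stop("fixed-effect design rank deficient on the observed subset")
  Go <- unclass(grm)[o, o]
  eg <- eigen((Go + t(Go)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, yo)
  Xt <- crossprod(U, Xo)
  nq <- length(o) - ncol(Xo)

  negll <- function(loglam) {
    lam <- exp(loglam)
    h <- lam * d + 1
    w <- 1 / h
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    rss <- sum(r^2 * w)
    s2e <- rss / nq
    0.5 * (nq * log(s2e) + sum(log(h)) +
             determinant(XtWX, logarithm = TRUE)$modulus + nq)
  }
  opt <- stats::optimize(negll, c(-12, 12), tol = 1e-9)
  if (!is.finite(opt$objective)) stop("REML optimization failed to converge")
  lam <- exp(opt$minimum)
  h <- lam * d + 1
  w <- 1 / h
  XtWX <- crossprod(Xt, Xt * w)
  beta <- solve(XtWX, crossprod(Xt, yt * w))
  r <- yt - Xt %*% beta
  s2e <- sum(r^2 * w) / nq
  s2a <- lam * s2e
  # BLUP: g_hat = s2a * G[, o] %*% Vinv %*% (y_o - X_o b), via the spectrum
  vinv_r <- U %*% (r / (s2a * d + s2e))
  gebv <- s2a * unclass(grm)[, o] %*% vinv_r
  structure(list(method = "stgblup", sigma2_a = s2a, sigma2_e = s2e,
                 h2 = s2a / (s2a + s2e), loglik = -opt$objective,
                 b = stats::setNames(drop(beta), colnames(X)),
                 gebv = stats::setNames(drop(gebv), names(y))),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit (", x$method, ")\n", sep = "")
  if (x$method == "stgblup") {
    cat("  sigma2_a =", signif(x$sigma2_a, 5),
        " sigma2_e =", signif(x$sigma2_e, 5),
        " h2 =", round(x$h2, 3), "\n")
  } else {
    cat("  genetic (co)variance G0:\n"); print(round(x$G0, 5))
    cat("  residual variances:", signif(diag(x$R0), 5), "\n")
    if (nrow(x$G0) > 1)
      cat("  genetic correlation(s):",
          round(x$r_g[upper.tri(x$r_g)], 3), "\n")
  }
  cat("  REML loglik:", round(x$loglik, 3), "\n")
  invisible(x)
}

# lower-triangle index helper for G0 parameter packing
.lt_idx <- function(p) which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)

#' Multitrait GBLUP under the missing-by-design layout
#'
#' The same trait in different breeds is modeled as distinct traits with
#' genetic covariance `G0 (x) G`. Because no individual is observed for two
#' breed-traits, residual covariances across traits are not identifiable and
#' are fixed at zero. Variance components are estimated by
#' average-information REML with monotone step-halving safeguards (every
#' accepted step keeps the restricted likelihood non-decreasing; a failed AI
#' step falls back to a shortened gradient step), exploiting that each
#' individual contributes a single observed cell, so the observed-data
#' covariance is only n_obs x n_obs.
#'
#' @param pheno a `pheno_table` (validation individuals masked to `NA`).
#' @param grm a `grm` over all panel individuals, in `pheno$ids` order.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter maximum REML iterations.
#' @return A `gblup_fit` with `G0`, `R0` (diagonal), `r_g`
#'   (genetic correlation matrix), `loglik`, `loglik_path`, `b`, and `gebv`
#'   (n x p matrix over all individuals and breed-traits).
#' @export
fit_mtgblup <- function(pheno, grm, tol = 1e-8, max_iter = 200L) {
  Y <- pheno$Y
  p <- ncol(Y)
  breeds <- pheno$breeds
  G <- unclass(grm)
  n <- nrow(Y)
  if (p == 1L) {
    fit <- fit_stgblup(drop(Y[, 1]), pheno$X, grm)
    fit$method <- "mtgblup"
    fit$G0 <- matrix(fit$sigma2_a, 1, 1, dimnames = list(breeds, breeds))
    fit$R0 <- matrix(fit$sigma2_e, 1, 1, dimnames = list(breeds, breeds))
    fit$r_g <- matrix(1, 1, 1)
    fit$loglik_path <- fit$loglik
    fit$gebv <- matrix(fit$gebv, ncol = 1, dimnames = list(pheno$ids, breeds))
    return(fit)
  }
  cells <- which(!is.na(Y), arr.ind = TRUE)
  io <- cells[, 1]            # individual of each observed cell
  to <- cells[, 2]            # breed-trait of each observed cell
  no <- length(io)
  if (no < 3L * p) stop("too few observed cells for multitrait REML")
  yo <- Y[cells]
  # fixed effects: per-trait coefficients for every column of pheno$X
  q <- ncol(pheno$X)
  Xo <- matrix(0, no, q * p)
  for (t in seq_len(p)) {
    rows <- to == t
    Xo[rows, (t - 1L) * q + seq_len(q)] <- pheno$X[io[rows], , drop = FALSE]
  }
  keep <- qr(Xo)$rank
  if (keep < ncol(Xo)) {
    # drop all-zero / aliased columns (e.g. a trait fully masked in a fold)
    cs <- colSums(abs(Xo)) > 0
    Xo <- Xo[, cs, drop = FALSE]
    if (qr(Xo)$rank < ncol(Xo))
      stop("fixed-effect design rank deficient on the observed cells")
  }
  Goo <- G[io, io]

  # observed-data covariance is linear in the parameters:
  #   V = sum_{k<=l} G0[k,l] * Bg[[k,l]] + sum_t s2e_t * D_t
  lt <- .lt_idx(p)
  npar_g <- nrow(lt)
  Bg <- vector("list", npar_g)
  for (r in seq_len(npar_g)) {
    k <- lt[r, 1]; l <- lt[r, 2]
    ind <- if (k == l) outer(to == k, to == k) else
      outer(to == k, to == l) | outer(to == l, to == k)
    Bg[[r]] <- Goo * ind
  }
  vfun <- function(th) {
    V <- matrix(0, no, no)
    for (r in seq_len(npar_g)) V <- V + th[r] * Bg[[r]]
    diag(V) <- diag(V) + th[npar_g + to]
    V
  }
  remll <- function(th) {
    V <- vfun(th)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    Vinv <- chol2inv(U)
    XtVX <- crossprod(Xo, Vinv %*% Xo)
    U2 <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(U2)) return(NULL)
    beta <- chol2inv(U2) %*% crossprod(Xo, Vinv %*% yo)
    r <- yo - Xo %*% beta
    Pr <- Vinv %*% r
    ll <- -0.5 * (2 * sum(log(diag(U))) + 2 * sum(log(diag(U2))) +
                    sum(r * Pr))
    P <- Vinv - (Vinv %*% Xo) %*% chol2inv(U2) %*% crossprod(Xo, Vinv)
    list(ll = ll, P = P, Pr = P %*% r, beta = beta, Vinv = Vinv, r = r)
  }
  valid <- function(th) {
    G0 <- matrix(0, p, p)
    G0[cbind(lt[, 1], lt[, 2])] <- th[seq_len(npar_g)]
    G0[cbind(lt[, 2], lt[, 1])] <- th[seq_len(npar_g)]
    all(th[npar_g + seq_len(p)] > 0) &&
      !is.null(tryCatch(chol(G0 + diag(1e-12, p)), error = function(e) NULL))
  }

  # start: within-trait variances split half genetic / half residual
  v0 <- apply(Y, 2, stats::var, na.rm = TRUE)
  v0[!is.finite(v0) | v0 <= 0] <- mean(v0, na.rm = TRUE)
  th <- c(ifelse(lt[, 1] == lt[, 2], 0.5 * v0[lt[, 1]], 0), 0.5 * v0)
  cur <- remll(th)
  if (is.null(cur)) stop("initial covariance not positive definite")
  path <- cur$ll
  npar <- length(th)
  for (it in seq_len(max_iter)) {
    # gradient and average-information matrix
    gr <- numeric(npar)
    W <- vector("list", npar)       # V_k %*% Pr
    for (r in seq_len(npar_g)) W[[r]] <- Bg[[r]] %*% cur$Pr
    for (t in seq_len(p)) W[[npar_g + t]] <- (to == t) * cur$Pr
    for (r in seq_len(npar)) {
      trPV <- if (r <= npar_g) sum(cur$P * Bg[[r]]) else
        sum(diag(cur$P)[to == r - npar_g])
      gr[r] <- -0.5 * (trPV - sum(cur$Pr * W[[r]]))
    }
    AI <- matrix(0, npar, npar)
    PW <- lapply(W, function(wk) cur$P %*% wk)
    for (r in seq_len(npar)) for (s2 in r:npar)
      AI[r, s2] <- AI[s2, r] <- 0.5 * sum(W[[r]] * PW[[s2]])
    step <- tryCatch(solve(AI + diag(1e-10 * max(diag(AI)), npar), gr),
                     error = function(e) gr / max(abs(gr), 1))
    # monotone safeguard: halve until valid and non-decreasing
    ok <- FALSE
    for (hh in 0:30) {
      thn <- th + step / 2^hh
      if (!valid(thn)) next
      nxt <- remll(thn)
      if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-12) {
        ok <- TRUE; break
      }
    }
    if (!ok) break                  # no admissible uphill step left
    dll <- nxt$ll - cur$ll
    th <- thn; cur <- nxt
    path <- c(path, cur$ll)
    if (dll < tol && max(abs(gr)) < 1e-4) break
  }

  G0 <- matrix(0, p, p, dimnames = list(breeds, breeds))
  G0[cbind(lt[, 1], lt[, 2])] <- th[seq_len(npar_g)]
  G0[cbind(lt[, 2], lt[, 1])] <- th[seq_len(npar_g)]
  s2e <- th[npar_g + seq_len(p)]
  # GEBVs for every individual x breed-trait through the GRM columns
  w <- drop(cur$Vinv %*% cur$r)
  gebv <- matrix(0, n, p, dimnames = list(pheno$ids, breeds))
  for (k in seq_len(p)) {
    accum <- numeric(n)
    for (t in seq_len(p)) {
      rows <- which(to == t)
      if (length(rows))
        accum <- accum + G0[k, t] * drop(G[, io[rows], drop = FALSE] %*%
                                           w[rows])
    }
    gebv[, k] <- accum
  }
  d <- sqrt(diag(G0))
  r_g <- G0 / tcrossprod(pmax(d, .Machine$double.eps))
  structure(list(method = "mtgblup", G0 = G0,
                 R0 = diag(s2e, p, p), r_g = r_g,
                 loglik = cur$ll, loglik_path = path,
                 b = drop(cur$beta), gebv = gebv, iterations = it),
            class = "gblup_fit")
}
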