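// Hot loop of the blockwise multitrait BayesA Gibbs sampler: per-SNP
// p-variate effect draws with incremental residual updates. Uses R's RNG
// (norm_rand) so runs are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static arma::mat chol_upper_safe(const arma::mat& S, int block) {
  arma::mat Ssym = 0.5 * (S + S.t());
  arma::mat U;
  if (arma::chol(U, Ssym)) return U;
  Ssym.diag() += 1e-10 * arma::trace(Ssym) + 1e-300;
  if (arma::chol(U, Ssym)) return U;
  Rcpp::stop("non-positive-definite conditional covariance in block %d",
             block);
  return U;  // not reached
}

// Draw effects for every SNP in the given blocks (1-based inclusive column
// ranges of M). A (m x p) and E (n x p) are updated and returned.
// [[Rcpp::export]]
Rcpp::List gibbs_effects_cpp(const arma::mat& M, arma::mat A, arma::mat E,
                             const arma::cube& G, const arma::mat& R0,
                             const arma::ivec& first, const arma::ivec& last) {
  const arma::uword p = A.n_cols;
  const arma::uword s = first.n_elem;
  arma::mat R0inv = arma::inv_sympd(0.5 * (R0 + R0.t()));
  arma::vec z(p), rhs(p), mu(p), anew(p);
  for (arma::uword b = 0; b < s; ++b) {
    arma::mat Ginv;
    if (!arma::inv_sympd(Ginv, 0.5 * (G.slice(b) + G.slice(b).t()))) {
      arma::mat Gj = 0.5 * (G.slice(b) + G.slice(b).t());
      Gj.diag() += 1e-10 * arma::trace(Gj) + 1e-300;
      if (!arma::inv_sympd(Ginv, Gj))
        Rcpp::stop("singular block covariance in block %d", (int)(b + 1));
    }
    for (arma::uword j = (arma::uword)first[b] - 1;
         j <= (arma::uword)last[b] - 1; ++j) {
      arma::vec mj = M.col(j);
      double xtx = arma::dot(mj, mj);
      arma::rowvec aold = A.row(j);
      rhs = R0inv * (E.t() * mj + xtx * aold.t());
      arma::mat prec = xtx * R0inv + Ginv;
      arma::mat U = chol_upper_safe(prec, (int)(b + 1));
      // mu solves prec * mu = rhs via the factor
      mu = arma::solve(arma::trimatu(U),
                       arma::solve(arma::trimatl(U.t()), rhs));
      for (arma::uword k = 0; k < p; ++k) z[k] = norm_rand();
      anew = mu + arma::solve(arma::trimatu(U), z);
      E -= mj * (anew.t() - aold);
      A.row(j) = anew.t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("E") = E);
}

// Marginalized variant for the missing-by-design layout with diagonal
// residual covariance: only observed cells (Obs = 1) enter the likelihood,
// so the per-trait precision uses the per-trait SNP sums of squares Xtx
// and residuals are tracked at observed cells only (E is 0 elsewhere).
// [[Rcpp::export]]
Rcpp::List gibbs_effects_masked_cpp(const arma::mat& M, arma::mat A,
                                    arma::mat E, const arma::cube& G,
                                    const arma::vec& s2e,
                                    const arma::ivec& first,
                                    const arma::ivec& last,
                                    const arma::mat& Obs,
                                    const arma::mat& Xtx) {
  const arma::uword p = A.n_cols;
  const arma::uword s = first.n_elem;
  arma::vec z(p), rhs(p), mu(p), anew(p);
  for (arma::uword b = 0; b < s; ++b) {
    arma::mat Ginv;
    if (!arma::inv_sympd(Ginv, 0.5 * (G.slice(b) + G.slice(b).t()))) {
      arma::mat Gj = 0.5 * (G.slice(b) + G.slice(b).t());
      Gj.diag() += 1e-10 * arma::trace(Gj) + 1e-300;
      if (!arma::inv_sympd(Ginv, Gj))
        Rcpp::stop("singular block covariance in block %d", (int)(b + 1));
    }
    for (arma::uword j = (arma::uword)first[b] - 1;
         j <= (arma::uword)last[b] - 1; ++j) {
      arma::vec mj = M.col(j);
      arma::rowvec aold = A.row(j);
      // E is zero at unobserved cells, so E' mj sums observed rows only
      arma::vec em = E.t() * mj;
      arma::mat prec = Ginv;
      for (arma::uword l = 0; l < p; ++l) {
        rhs[l] = (em[l] + Xtx(j, l) * aold[l]) / s2e[l];
        prec(l, l) += Xtx(j, l) / s2e[l];
      }
      arma::mat U = chol_upper_safe(prec, (int)(b + 1));
      mu = arma::solve(arma::trimatu(U),
                       arma::solve(arma::trimatl(U.t()), rhs));
      for (arma::uword k = 0; k < p; ++k) z[k] = norm_rand();
      anew = mu + arma::solve(arma::trimatu(U), z);
      E -= (mj * (anew.t() - aold)) % Obs;
      A.row(j) = anew.t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("E") = E);
}
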