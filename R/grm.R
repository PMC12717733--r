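#' VanRaden genomic relationship matrix
#'
#' First-method GRM `G = ZZ' / (2 sum p_j (1 - p_j))` with `Z` the dosage
#' matrix column-centered by twice the allele frequency of the joint
#' (merged) reference population. Monomorphic SNPs contribute zero to the
#' numerator and are excluded from the denominator.
#'
#' @param panel merged `genotype_panel` (no missing dosages by construction).
#' @return An n x n matrix of class `grm` with attributes `af` (allele
#'   frequencies used) and `denom` (the scaling denominator).
#' @export
build_grm <- function(panel) {
  af <- allele_freq(panel)
  poly <- af > 0 & af < 1
  if (!any(poly)) stop("all SNPs are monomorphic; GRM undefined")
  Z <- sweep(panel$geno, 2, 2 * af)
  denom <- 2 * sum(af[poly] * (1 - af[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(panel$fam$id, panel$fam$id)
  structure(G, af = af, denom = denom, class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x), "individuals; mean diagonal",
      round(mean(diag(x)), 4), "\n")
  invisible(unclass(x))
}
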