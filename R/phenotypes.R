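#' Phenotype tables in the stacked multibreed layout
#'
#' In the multitrait formulation the same trait measured in different breeds
#' is treated as distinct, correlated traits. Each genotyped individual has an
#' observed value for its own breed-trait only; all other breed-trait cells
#' are structurally missing and are imputed by data augmentation during
#' Gibbs sampling. `phenotype_table()` builds this layout from per-record
#' data; `read_phenotypes()` reads the records from a delimited file.
#'
#' @param records data.frame with columns `id`, `breed`, the trait column and
#'   any covariate columns. One record per phenotyped individual.
#' @param panel the `genotype_panel` the records refer to.
#' @param trait name of the trait column. Defaults to the first column that
#'   is neither `id`, `breed` nor a covariate.
#' @param covariates character vector of covariate column names included as
#'   fixed effects (e.g. `"sex"`); the per-breed population mean is always
#'   fitted and need not be listed.
#' @return An object of class `pheno_table` with elements `Y` (individuals x
#'   breed-traits matrix, `NA` = missing), `X` (fixed-effect design:
#'   intercept plus covariates, coefficients are per breed-trait), `breeds`,
#'   `ids` and the original `records`. Individuals in the panel without a
#'   record get an all-missing row (e.g. validation candidates).
#' @export
phenotype_table <- function(records, panel, trait = NULL, covariates = NULL) {
  if (!all(c("id", "breed") %in% names(records)))
    stop("records need columns id and breed")
  if (is.null(trait)) {
    cand <- setdiff(names(records), c("id", "breed", covariates))
    if (!length(cand)) stop("no trait column found")
    trait <- cand[1]
  }
  if (!trait %in% names(records)) stop("no column named ", trait)
  unknown <- setdiff(records$id, panel$fam$id)
  if (length(unknown))
    stop("phenotype record(s) for sample(s) absent from panel: ",
         paste(unknown, collapse = ", "))
  v <- records[[trait]]
  if (!is.numeric(v)) {
    vn <- suppressWarnings(as.numeric(ifelse(v %in% c("NA", ""), NA, v)))
    bad <- !is.na(v) & !(v %in% c("NA", "")) & is.na(vn)
    if (any(bad))
      stop("non-numeric trait value(s): ", paste(unique(v[bad]), collapse = ", "))
    v <- vn
  }
  pb <- panel$fam$breed[match(records$id, panel$fam$id)]
  if (any(pb != records$breed))
    stop("breed label mismatch with panel for sample(s): ",
         paste(records$id[pb != records$breed], collapse = ", "))
  breeds <- sort(unique(panel$fam$breed))
  n <- nrow(panel$fam)
  Y <- matrix(NA_real_, n, length(breeds),
              dimnames = list(panel$fam$id, breeds))
  Y[cbind(match(records$id, panel$fam$id), match(records$breed, breeds))] <- v
  X <- matrix(1, n, 1, dimnames = list(panel$fam$id, "mean"))
  for (cv in covariates) {
    if (!cv %in% names(records)) stop("no covariate column ", cv)
    col <- rep(NA_real_, n)
    col[match(records$id, panel$fam$id)] <- as.numeric(records[[cv]])
    # validation individuals lack covariates; centre so 0 is neutral
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    X <- cbind(X, stats::setNames(col, NULL))
    colnames(X)[ncol(X)] <- cv
  }
  structure(list(Y = Y, X = X, breeds = breeds, ids = panel$fam$id,
                 trait = trait, records = records),
            class = "pheno_table")
}

#' @rdname phenotype_table
#' @param path delimited text file (whitespace or comma separated) with a
#'   header row; missing trait values are coded `NA`.
#' @export
read_phenotypes <- function(path, panel, trait = NULL, covariates = NULL) {
  l1 <- readLines(path, n = 1)
  sep <- if (grepl(",", l1)) "," else ""
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "NA")
  phenotype_table(rec, panel, trait = trait, covariates = covariates)
}

#' @export
print.pheno_table <- function(x, ...) {
  cat("pheno_table:", nrow(x$Y), "individuals,", length(x$breeds),
      "breed-trait(s) [", paste(x$breeds, collapse = ", "), "]\n")
  cat("  observed cells:", sum(!is.na(x$Y)), " fixed-effect columns:",
      ncol(x$X), "\n")
  invisible(x)
}

#' Mask phenotypes of validation individuals
#'
#' Sets every breed-trait cell of the given individuals to missing, as done
#' for the validation fold during cross-validation.
#'
#' @param pheno a `pheno_table`.
#' @param ids sample ids to mask.
#' @return The masked `pheno_table`.
#' @export
mask_phenotypes <- function(pheno, ids) {
  i <- match(ids, pheno$ids)
  if (anyNA(i)) stop("unknown sample id(s) in mask")
  pheno$Y[i, ] <- NA_real_
  pheno
}
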