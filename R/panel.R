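#' Genotype panel objects
#'
#' A `genotype_panel` bundles an integer dosage matrix (individuals x SNPs,
#' counting copies of the minor allele as defined on the merged panel), a
#' variant map and per-sample metadata including the breed label. It is the
#' container consumed by every downstream function in the package.
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns; entries
#'   must be 0, 1 or 2. Row names are sample ids, column names SNP ids.
#' @param map data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`; one
#'   row per SNP, in column order of `geno`. `a1` is the counted allele.
#' @param fam data.frame with columns `id`, `breed` and optionally `sex`; one
#'   row per individual, in row order of `geno`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, map, fam) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (anyNA(geno))
    stop("genotype matrix contains missing calls; missingness is rejected")
  if (!all(geno %in% 0:2))
    stop("dosages must be 0, 1 or 2 (minor-allele copies)")
  stopifnot(nrow(map) == ncol(geno), nrow(fam) == nrow(geno))
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(map))) stop("map needs columns id, chrom, pos")
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  if (!all(c("id", "breed") %in% names(fam)))
    stop("fam needs columns id and breed")
  if (anyNA(fam$breed) || any(fam$breed == ""))
    stop("every sample needs exactly one breed label; missing for: ",
         paste(fam$id[is.na(fam$breed) | fam$breed == ""], collapse = ", "))
  # variants must be strictly ordered by (chromosome, position)
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_len(nrow(map))))
    stop("variants must be ordered by (chromosome, position)")
  rownames(geno) <- fam$id
  colnames(geno) <- map$id
  structure(list(geno = geno, map = map, fam = fam),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs\n")
  cat("  chromosomes:", length(unique(x$map$chrom)),
      " breeds:", paste(sprintf("%s (%d)", names(table(x$fam$breed)),
                                table(x$fam$breed)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Subset a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param samples optional sample ids or logical/integer row index.
#' @param snps optional SNP ids or logical/integer column index.
#' @return A `genotype_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  ri <- seq_len(nrow(panel$geno))
  ci <- seq_len(ncol(panel$geno))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, panel$fam$id) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id(s)")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, panel$map$id) else ci[snps]
    if (anyNA(ci)) stop("unknown SNP id(s)")
  }
  genotype_panel(panel$geno[ri, ci, drop = FALSE],
                 panel$map[ci, , drop = FALSE],
                 panel$fam[ri, , drop = FALSE])
}

#' Merged-panel minor allele frequencies
#'
#' Frequency of the counted allele across all breeds, i.e. on the merged
#' panel. Used by the prior scale matrices, the relationship matrix and the
#' minor-allele recoding.
#'
#' @param panel a `genotype_panel`.
#' @return numeric vector of allele frequencies, one per SNP.
#' @export
allele_freq <- function(panel) colMeans(panel$geno) / 2

#' Recode dosages to merged-panel minor-allele counts
#'
#' Flips any SNP whose counted allele has frequency > 0.5 on the merged panel
#' (dosage becomes `2 - dosage`, allele labels swap). Frequencies of exactly
#' 0.5 are left as stored.
#'
#' @param panel a `genotype_panel`.
#' @return A recoded `genotype_panel`.
#' @export
recode_minor <- function(panel) {
  p <- allele_freq(panel)
  flip <- p > 0.5
  if (any(flip)) {
    panel$geno[, flip] <- 2L - panel$geno[, flip, drop = FALSE]
    a1 <- panel$map$a1
    panel$map$a1[flip] <- panel$map$a2[flip]
    panel$map$a2[flip] <- a1[flip]
  }
  panel
}

## ---- PLINK 1 binary ---------------------------------------------------

# 2-bit PLINK codes, SNP-major: 00 hom a1, 10 het, 11 hom a2, 01 missing.
# Dosage counts copies of a1 (the .bim allele-1).
.plink_lut <- {
  lut <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      lut[b + 1, k + 1] <- switch(code + 1L, 2L, NA_integer_, 1L, 0L)
    }
  }
  lut
}

#' Read a PLINK 1 binary fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triplet, attaches breed labels from a sidecar
#' table and recodes dosages to minor-allele counts on the merged panel.
#' Missing genotype calls are rejected with an error naming the first
#' offending SNP and sample.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @param breed_map data.frame with columns `id` and `breed` covering every
#'   sample in the `.fam` file. Breed labels deliberately come from this
#'   sidecar table rather than the `.fam` family-id column.
#' @return A `genotype_panel` with dosages coded 0/1/2 minor-allele copies.
#' @export
read_plink <- function(prefix, breed_map) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimt <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  famt <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("fid", "id", "pat", "mat", "sex", "phe"))
  n <- nrow(famt); m <- nrow(bimt)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  # expand each byte to 4 dosages, then trim padding rows
  geno <- matrix(NA_integer_, n, m)
  for (k in 1:4) {
    rows <- seq.int(k, by = 4, length.out = bpv)
    keep <- rows <= n
    if (any(keep))
      geno[rows[keep], ] <- .plink_lut[body[keep, , drop = FALSE] + 1L, k]
  }
  if (anyNA(geno)) {
    idx <- which(is.na(geno), arr.ind = TRUE)[1, ]
    stop("missing genotype call at SNP ", bimt$id[idx[2]],
         ", sample ", famt$id[idx[1]],
         "; genotype missingness is not supported")
  }
  miss <- setdiff(famt$id, breed_map$id)
  if (length(miss))
    stop("breed_map lacks entries for sample(s): ", paste(miss, collapse = ", "))
  br <- breed_map$breed[match(famt$id, breed_map$id)]
  if (anyNA(br) || any(br == ""))
    stop("empty breed label for sample(s): ",
         paste(famt$id[is.na(br) | br == ""], collapse = ", "))
  map <- data.frame(id = bimt$id, chrom = bimt$chrom, pos = bimt$pos,
                    a1 = bimt$a1, a2 = bimt$a2, stringsAsFactors = FALSE)
  famd <- data.frame(id = famt$id, breed = br, sex = famt$sex,
                     stringsAsFactors = FALSE)
  recode_minor(genotype_panel(geno, map, famd))
}

#' Write a genotype panel as a PLINK 1 binary fileset
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- nrow(panel$geno); m <- ncol(panel$geno)
  bimt <- data.frame(panel$map$chrom, panel$map$id, 0, panel$map$pos,
                     panel$map$a1, panel$map$a2)
  utils::write.table(bimt, paste0(prefix, ".bim"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  sex <- if (is.null(panel$fam$sex)) rep(0L, n) else panel$fam$sex
  famt <- data.frame(panel$fam$breed, panel$fam$id, 0, 0, sex, -9)
  utils::write.table(famt, paste0(prefix, ".fam"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  # dosage (a1 copies) -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11
  code <- matrix(c(3L, 2L, 0L)[panel$geno + 1L], n, m)
  bpv <- ceiling(n / 4)
  pad <- bpv * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  k <- seq.int(1, bpv * 4L, by = 4L)
  bytes <- code[k, , drop = FALSE] +
    4L * code[k + 1L, , drop = FALSE] +
    16L * code[k + 2L, , drop = FALSE] +
    64L * code[k + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
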