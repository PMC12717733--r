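#' Block maps: genome partitions into contiguous SNP blocks
#'
#' A `block_map` is an ordered set of non-overlapping SNP-index intervals
#' that tile every chromosome exactly. Indices are 1-based inclusive column
#' indices into the genotype panel the map was built from.
#'
#' @param blocks data.frame with columns `chrom`, `first`, `last` (global
#'   1-based inclusive SNP column indices).
#' @param chrom_sizes named integer vector of SNPs per chromosome, in panel
#'   order; used to verify that the blocks tile each chromosome.
#' @param method partition provenance, `"ld"` or `"fixed"`.
#' @param params list of the parameters used (e.g. `n_win`, `spar`, or
#'   `block_size`).
#' @return An object of class `block_map` (a data.frame with columns
#'   `chrom`, `first`, `last`, `n_snps` and attributes `method`, `params`).
#' @export
block_map <- function(blocks, chrom_sizes, method = "ld", params = list()) {
  stopifnot(all(c("chrom", "first", "last") %in% names(blocks)))
  blocks <- blocks[order(blocks$first), , drop = FALSE]
  blocks$n_snps <- blocks$last - blocks$first + 1L
  if (any(blocks$n_snps < 1L)) stop("empty block")
  off <- c(0L, cumsum(as.integer(chrom_sizes)))
  for (ci in seq_along(chrom_sizes)) {
    b <- blocks[blocks$chrom == names(chrom_sizes)[ci], , drop = FALSE]
    lo <- off[ci] + 1L; hi <- off[ci + 1L]
    if (nrow(b) == 0L || b$first[1] != lo || b$last[nrow(b)] != hi ||
        (nrow(b) > 1L && any(b$first[-1] != b$last[-nrow(b)] + 1L)))
      stop("blocks do not tile chromosome ", names(chrom_sizes)[ci])
  }
  if (sum(blocks$n_snps) != sum(chrom_sizes))
    stop("blocks do not cover every SNP exactly once")
  rownames(blocks) <- NULL
  structure(blocks[, c("chrom", "first", "last", "n_snps")],
            method = method, params = params, chrom_sizes = chrom_sizes,
            class = c("block_map", "data.frame"))
}

#' @export
print.block_map <- function(x, ...) {
  cat("block_map (", attr(x, "method"), "): ", nrow(x), " blocks over ",
      length(attr(x, "chrom_sizes")), " chromosome(s), ",
      sum(x$n_snps), " SNPs; block sizes ", min(x$n_snps), "-",
      max(x$n_snps), " (median ", stats::median(x$n_snps), ")\n", sep = "")
  invisible(x)
}

#' Fixed-size genome partition
#'
#' Consecutive runs of `block_size` SNPs per chromosome; the final block of a
#' chromosome holds the remainder. Blocks never cross chromosome boundaries.
#' This is the comparator partition for the fixed-block Bayesian model.
#'
#' @param n_snps_per_chrom named integer vector of SNPs per chromosome.
#' @param block_size SNPs per block (default 100).
#' @return A `block_map` with method `"fixed"`.
#' @export
partition_fixed <- function(n_snps_per_chrom, block_size = 100L) {
  stopifnot(block_size >= 1L)
  off <- 0L
  rows <- list()
  for (ci in seq_along(n_snps_per_chrom)) {
    m <- as.integer(n_snps_per_chrom[ci])
    first <- seq.int(1L, m, by = block_size)
    last <- pmin(first + block_size - 1L, m)
    rows[[ci]] <- data.frame(chrom = names(n_snps_per_chrom)[ci],
                             first = off + first, last = off + last)
    off <- off + m
  }
  block_map(do.call(rbind, rows), n_snps_per_chrom, method = "fixed",
            params = list(block_size = as.integer(block_size)))
}

#' Write / read a block map
#'
#' Serialized as a tab-separated table with header
#' `chrom first last n_snps method`; SNP indices are 1-based inclusive.
#'
#' @param bm a `block_map`.
#' @param path output file.
#' @return `path` invisibly (write); a `block_map` (read).
#' @export
write_blockmap <- function(bm, path) {
  out <- data.frame(chrom = bm$chrom, first = bm$first, last = bm$last,
                    n_snps = bm$n_snps, method = attr(bm, "method"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blockmap
#' @export
read_blockmap <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sizes <- tapply(tb$n_snps, tb$chrom, sum)
  ord <- unique(tb$chrom)
  sizes <- stats::setNames(as.integer(sizes[ord]), ord)
  block_map(tb[, c("chrom", "first", "last")], sizes,
            method = tb$method[1], params = list())
}
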