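#' Windowed LD statistic for breakpoint detection
#'
#' For every candidate breakpoint k on a chromosome, `compute_w()` averages
#' the squared Pearson correlations of all dosage-column pairs (i, j) that
#' span k (i <= k < j) with both members within `n_win` SNPs of k and of
#' each other. Low values of w mark positions where LD between the two
#' flanking haplotype stretches is weak, i.e. natural block boundaries.
#' The statistic is computed on the merged (all-breed) panel.
#'
#' Pairs involving a monomorphic column (undefined correlation) are excluded
#' and the pair count reduced; if no valid pair remains, w is missing at that
#' position and later bridged by the smoother.
#'
#' @param panel merged `genotype_panel`.
#' @param chrom chromosome identifier (must match `panel$map$chrom`).
#' @param n_win window half-width in SNPs (default 50).
#' @return An object of class `w_profile`: list with `chrom`, `w_raw`
#'   (length = SNPs on the chromosome; last entry `NA` since no pair spans
#'   the final SNP), `m_pairs` (valid pair counts), `n_win`, and `w_smooth`
#'   (`NULL` until [smooth_w()] is called).
#' @seealso [smooth_w()], [find_breakpoints()], [partition_genome()]
#' @export
compute_w <- function(panel, chrom, n_win = 50L) {
  stopifnot(n_win >= 1L)
  cols <- which(panel$map$chrom == chrom)
  m <- length(cols)
  if (m < 2L) stop("chromosome ", chrom, " has fewer than 2 SNPs")
  G <- panel$geno[, cols, drop = FALSE]
  n <- nrow(G)
  sds <- apply(G, 2, stats::sd)
  ok <- sds > 0
  Z <- matrix(0, n, m)
  Z[, ok] <- scale(G[, ok, drop = FALSE])
  num <- numeric(m)
  cnt <- integer(m)
  # pair (i, i + d), d <= n_win, contributes to every k in i .. i+d-1
  for (d in seq_len(min(n_win, m - 1L))) {
    i <- seq_len(m - d)
    r2 <- (colSums(Z[, i, drop = FALSE] * Z[, i + d, drop = FALSE]) / (n - 1))^2
    valid <- ok[i] & ok[i + d]
    r2[!valid] <- 0
    cr <- c(0, cumsum(r2))
    cv <- c(0L, cumsum(as.integer(valid)))
    k <- seq_len(m - 1L)
    hi <- pmin(k, m - d)
    lo <- pmax(1L, k - d + 1L)
    any_ <- hi >= lo
    num[k][any_] <- num[k][any_] + (cr[hi + 1L] - cr[lo])[any_]
    cnt[k][any_] <- cnt[k][any_] + (cv[hi + 1L] - cv[lo])[any_]
  }
  w <- ifelse(cnt > 0L, num / pmax(cnt, 1L), NA_real_)
  w[m] <- NA_real_
  structure(list(chrom = chrom, w_raw = w, m_pairs = cnt,
                 n_win = as.integer(n_win), spar = NULL, w_smooth = NULL),
            class = "w_profile")
}

#' @export
print.w_profile <- function(x, ...) {
  cat("w_profile for chromosome", x$chrom, ":", length(x$w_raw),
      "SNPs, n_win =", x$n_win, "\n")
  if (!is.null(x$w_smooth)) cat("  smoothed (spar =", x$spar, ")\n")
  invisible(x)
}

#' @export
as.data.frame.w_profile <- function(x, ...) {
  data.frame(chrom = x$chrom, snp = seq_along(x$w_raw), w_raw = x$w_raw,
             m_pairs = x$m_pairs,
             w_smooth = if (is.null(x$w_smooth)) NA_real_ else x$w_smooth)
}

#' Smooth a w profile with a cubic smoothing spline
#'
#' Applies [stats::smooth.spline()] with the given `spar` to the raw w
#' values, interpolating through positions where w was undefined. With fewer
#' than 4 defined points the raw curve is passed through with a warning.
#'
#' @param profile a `w_profile` from [compute_w()].
#' @param spar smoothing parameter of [stats::smooth.spline()]
#'   (default 0.2, a moderate smoothing for ~50K-density panels).
#' @param df optional effective degrees of freedom passed straight to
#'   [stats::smooth.spline()] instead of `spar`.
#' @return The profile with `w_smooth` filled in.
#' @export
smooth_w <- function(profile, spar = 0.2, df = NULL) {
  w <- profile$w_raw
  m <- length(w)
  idx <- which(!is.na(w))
  if (length(idx) < 4L) {
    warning("fewer than 4 defined w values; smoothing skipped")
    profile$w_smooth <- w
    profile$spar <- spar
    return(profile)
  }
  fit <- if (is.null(df))
    stats::smooth.spline(idx, w[idx], spar = spar)
  else stats::smooth.spline(idx, w[idx], df = df)
  sm <- rep(NA_real_, m)
  sm[seq_len(m - 1L)] <- stats::predict(fit, seq_len(m - 1L))$y
  profile$w_smooth <- sm
  profile$spar <- if (is.null(df)) spar else NA_real_
  profile
}

# strict interior local minima with deterministic plateau handling: a flat
# run lower than both neighbouring runs yields one breakpoint at its last
# index; chromosome ends are never breakpoints.
local_minima <- function(s) {
  len <- length(s)
  if (len < 3L) return(integer(0))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  nr <- length(r$values)
  if (nr < 3L) return(integer(0))
  mins <- which(r$values[2:(nr - 1L)] < r$values[1:(nr - 2L)] &
                  r$values[2:(nr - 1L)] < r$values[3:nr]) + 1L
  ends[mins]
}

#' Breakpoints from a smoothed w profile
#'
#' Every strict interior local minimum of the smoothed curve becomes a
#' breakpoint; block i runs from the SNP after the previous breakpoint
#' through the breakpoint SNP, and the last block runs to the chromosome
#' end. A monotone curve yields a single block.
#'
#' @param profile a smoothed `w_profile`.
#' @return A single-chromosome `block_map` (1-based local SNP indices).
#' @export
find_breakpoints <- function(profile) {
  if (is.null(profile$w_smooth)) stop("profile is not smoothed; call smooth_w()")
  m <- length(profile$w_raw)
  s <- profile$w_smooth[seq_len(m - 1L)]
  bp <- local_minima(s)  # never in the first or last run, so 2 <= bp <= m-2
  first <- c(1L, bp + 1L)
  last <- c(bp, m)
  sizes <- stats::setNames(m, profile$chrom)
  block_map(data.frame(chrom = profile$chrom, first = first, last = last),
            sizes, method = "ld",
            params = list(n_win = profile$n_win, spar = profile$spar))
}

#' Partition a genome into LD blocks
#'
#' Runs the full partitioning pipeline per chromosome on the merged panel —
#' w statistic, spline smoothing, local-minima breakpoints — or the
#' fixed-size comparator, and concatenates the per-chromosome maps.
#' Chromosomes with a single SNP become single blocks.
#'
#' @param panel merged `genotype_panel` (reference individuals of all breeds).
#' @param method `"ld"` (default) or `"fixed"`.
#' @param n_win,spar LD-method parameters, see [compute_w()] and [smooth_w()].
#' @param block_size fixed-method block size (default 100).
#' @return A `block_map` covering the whole panel.
#' @export
partition_genome <- function(panel, method = c("ld", "fixed"),
                             n_win = 50L, spar = 0.2, block_size = 100L) {
  method <- match.arg(method)
  chroms <- unique(panel$map$chrom)
  sizes <- stats::setNames(
    as.integer(table(factor(panel$map$chrom, levels = chroms))), chroms)
  if (method == "fixed") return(partition_fixed(sizes, block_size))
  off <- 0L
  rows <- list()
  for (ch in chroms) {
    m <- sizes[[ch]]
    if (m == 1L) {
      rows[[ch]] <- data.frame(chrom = ch, first = off + 1L, last = off + 1L)
    } else {
      prof <- smooth_w(compute_w(panel, ch, n_win = n_win), spar = spar)
      bm <- find_breakpoints(prof)
      rows[[ch]] <- data.frame(chrom = ch, first = off + bm$first,
                               last = off + bm$last)
    }
    off <- off + m
  }
  block_map(do.call(rbind, rows), sizes, method = "ld",
            params = list(n_win = as.integer(n_win), spar = spar))
}
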