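#' Write / read a GEBV table
#'
#' Tab-separated with header `id breed gebv [gebv_sd]`; values round-trip
#' at full double precision.
#'
#' @param tab data.frame as from [gebv_table()].
#' @param path output file.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_gebv <- function(tab, path) {
  stopifnot(all(c("id", "breed", "gebv") %in% names(tab)))
  fmt <- tab
  for (cc in names(fmt))
    if (is.numeric(fmt[[cc]])) fmt[[cc]] <- sprintf("%.17g", fmt[[cc]])
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gebv
#' @export
read_gebv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write posterior block (co)variances
#'
#' One row per block with the p(p+1)/2 distinct posterior-mean (co)variance
#' entries of that block's genetic covariance matrix (upper triangle,
#' column-labelled `var_<breed>` / `cov_<breed1>_<breed2>`).
#'
#' @param post an `mbgp_post`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_post_cov <- function(post, path) {
  p <- length(post$breeds)
  s <- dim(post$G)[3]
  cols <- list(block = seq_len(s))
  for (k in seq_len(p)) for (l in k:p) {
    nm <- if (k == l) paste0("var_", post$breeds[k]) else
      paste0("cov_", post$breeds[k], "_", post$breeds[l])
    cols[[nm]] <- post$G[k, l, ]
  }
  utils::write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
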