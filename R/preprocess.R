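#' Quantile-normalize an expression table
#'
#' Forces every sample column onto the same empirical distribution: the sorted
#' values of each column are replaced by the per-rank means of the
#' column-sorted input, and ties within a column receive the mean of their
#' rank targets. Delegates to [limma::normalizeQuantiles()] with tie handling.
#'
#' @param x Expression tibble.
#' @return Expression tibble of the same shape, normalized.
#' @export
quantile_normalize <- function(x) {
  m <- expr_matrix(x)
  if (ncol(m) < 1) abort("expression table has no sample columns")
  if (any(!is.finite(m))) abort("non-finite expression values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  expr_from_matrix(out)
}

#' Filter genes that never exceed a background fluorescence cutoff
#'
#' A gene is retained iff its maximum intensity across all samples exceeds
#' `cutoff` (raw fluorescence scale). The default cutoff of 136.5 units is the
#' level that excludes essentially all random-probe signal on the emulated
#' array design. Counts of removed/kept genes are reported via a message and
#' stored in attributes `n_kept` / `n_removed`.
#'
#' @param x Expression tibble on the raw (non-log) scale.
#' @param cutoff Background fluorescence cutoff (>= 0).
#' @param quiet Suppress the count message.
#' @return Filtered expression tibble.
#' @export
filter_background <- function(x, cutoff = 136.5, quiet = FALSE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    abort("`cutoff` must be a single non-negative number")
  }
  m <- expr_matrix(x)
  keep <- apply(m, 1, max) > cutoff
  out <- x[keep, , drop = FALSE]
  if (!quiet) {
    inform(sprintf("background filter (cutoff %g): kept %d genes, removed %d",
                   cutoff, sum(keep), sum(!keep)))
  }
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Collapse technical replicates to per-timepoint means
#'
#' Produces the per-timepoint expression profile used for co-expression
#' scoring: one column per Zeitgeber time, holding the mean across replicates.
#' Per-timepoint standard errors are attached as attribute `se` (a matrix of
#' the same shape) for plotting.
#'
#' @param x Expression tibble with replicate sample columns.
#' @return Expression tibble with one `ZT<hh>_r1`-style column per timepoint
#'   (labelled `ZT<hh>`), plus attribute `se`.
#' @export
collapse_replicates <- function(x) {
  info <- sample_info(x)
  m <- expr_matrix(x)
  zts <- sort(unique(info$zt))
  mean_mat <- matrix(NA_real_, nrow(m), length(zts))
  se_mat <- matrix(NA_real_, nrow(m), length(zts))
  for (i in seq_along(zts)) {
    cols <- info$sample[info$zt == zts[i]]
    sub <- m[, cols, drop = FALSE]
    mean_mat[, i] <- rowMeans(sub)
    se_mat[, i] <- if (ncol(sub) > 1) {
      apply(sub, 1, sd) / sqrt(ncol(sub))
    } else 0
  }
  labels <- sub("_r[0-9]+$", "", format_zt_label(zts, 1L))
  colnames(mean_mat) <- labels
  colnames(se_mat) <- labels
  rownames(mean_mat) <- rownames(m)
  out <- tibble(gene_id = rownames(m)) %>% dplyr::bind_cols(as_tibble(mean_mat))
  attr(out, "se") <- se_mat
  attr(out, "zt") <- zts
  out
}

# profile matrix (genes x timepoints) plus its timepoint hours, from either a
# replicate-level or an already-collapsed expression table
profile_matrix <- function(x) {
  if (!is.null(attr(x, "zt"))) {
    m <- as.matrix(x[setdiff(names(x), "gene_id")])
    rownames(m) <- x$gene_id
    return(list(values = m, zt = attr(x, "zt")))
  }
  info <- sample_info(x)
  list(values = expr_matrix(x), zt = info$zt)
}
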