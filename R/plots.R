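#' Plot a phase histogram of rhythmic genes
#'
#' Histogram of peak-phase (ZT) counts among rhythmic genes, in bins of
#' `bin_h` hours.
#'
#' @param results `rhythm_result` tibble from [jtk_detect()].
#' @param rhythmic_genes Optional gene ids to restrict to (e.g. from
#'   [classify_rhythmic()]); default: all genes with `q_value < 0.1`.
#' @param bin_h Bin width in hours (default 4).
#' @return A ggplot.
#' @export
plot_phase_histogram <- function(results, rhythmic_genes = NULL, bin_h = 4) {
  rhythmic_genes <- rhythmic_genes %||%
    results$gene_id[!is.na(results$q_value) & results$q_value < 0.1]
  df <- results[results$gene_id %in% rhythmic_genes & !is.na(results$phase_zt), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_zt)) +
    ggplot2::geom_histogram(breaks = seq(0, 24, by = bin_h),
                            closed = "left", fill = "grey35",
                            colour = "white") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, by = bin_h)) +
    ggplot2::labs(x = "Peak phase (ZT, h)", y = "Rhythmic genes",
                  title = "Phase distribution of rhythmic genes") +
    ggplot2::theme_minimal()
}

#' Plot a fold-change histogram of rhythmic genes
#'
#' @inheritParams plot_phase_histogram
#' @param bins Number of histogram bins (default 30).
#' @return A ggplot.
#' @export
plot_fold_change_histogram <- function(results, rhythmic_genes = NULL,
                                       bins = 30) {
  rhythmic_genes <- rhythmic_genes %||%
    results$gene_id[!is.na(results$q_value) & results$q_value < 0.1]
  df <- results[results$gene_id %in% rhythmic_genes &
                  !is.na(results$fold_change), ]
  med <- median(df$fold_change)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_change)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed") +
    ggplot2::labs(x = "Peak/trough fold change", y = "Rhythmic genes",
                  title = sprintf("Fold changes (median %.2f)", med)) +
    ggplot2::theme_minimal()
}

#' Autoplot a rhythm scan result
#'
#' Dispatches to [plot_phase_histogram()]; use `type = "fold_change"` for the
#' fold-change histogram.
#'
#' @param object `rhythm_result` tibble.
#' @param type `"phase"` (default) or `"fold_change"`.
#' @param ... Passed on to the underlying plot function.
#' @return A ggplot.
#' @method autoplot rhythm_result
#' @export
autoplot.rhythm_result <- function(object, type = c("phase", "fold_change"),
                                   ...) {
  type <- match.arg(type)
  if (type == "phase") plot_phase_histogram(object, ...)
  else plot_fold_change_histogram(object, ...)
}

#' Plot one gene's expression over the time course
#'
#' Replicate-level points, the per-timepoint mean line and, optionally, the
#' cosinor fit for a given period.
#'
#' @param x Expression tibble.
#' @param gene Gene id to plot.
#' @param period_h Cosine period to overlay; `NULL` (default) for none.
#' @param log2_scale Plot on log2 scale (default `TRUE`).
#' @return A ggplot.
#' @export
plot_gene_profile <- function(x, gene, period_h = NULL, log2_scale = TRUE) {
  check_expression_tbl(x)
  if (!gene %in% x$gene_id) abort(sprintf("gene '%s' not found", gene))
  info <- sample_info(x)
  y <- as.numeric(x[x$gene_id == gene, info$sample])
  if (log2_scale) y <- log2(y)
  df <- tibble(time = info$zt, value = y)
  means <- df %>%
    group_by(.data$time) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = means, colour = "grey30") +
    ggplot2::labs(x = "Time (h)",
                  y = if (log2_scale) "log2 expression" else "Expression",
                  title = gene) +
    ggplot2::theme_minimal()
  if (!is.null(period_h)) {
    fit <- cosinor_fit(df$value, df$time, period = period_h)
    grid <- tibble(time = seq(min(df$time), max(df$time), length.out = 200))
    w <- 2 * pi / period_h
    grid$value <- fit$mesor +
      fit$amplitude * cos(w * grid$time - w * fit$acrophase_zt)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Autoplot a cluster sweep
#'
#' The F-score curve over the K-percent rhythmic-fraction rule, with the
#' randomized null's 95th percentile band when a null matrix is supplied.
#'
#' @param object A `cluster_sweep`.
#' @param null_f Optional null F matrix from [randomized_cluster_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_sweep
#' @export
autoplot.cluster_sweep <- function(object, null_f = NULL, ...) {
  df <- object$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k_pct, y = .data$f_score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Minimum rhythmic fraction K (%)", y = "F-score",
                  title = "Cluster-based prediction sweep") +
    ggplot2::theme_minimal()
  if (!is.null(null_f)) {
    q95 <- apply(null_f, 2, function(v) {
      sort(v)[ceiling(0.95 * length(v))]
    })
    p <- p + ggplot2::geom_line(
      data = tibble(k_pct = df$k_pct, f_score = q95),
      linetype = "dashed", colour = "grey50"
    )
  }
  p
}

#' Autoplot a co-expression network
#'
#' Degree distribution of the network's non-isolated nodes.
#'
#' @param object A `coexpr_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coexpr_network
#' @export
autoplot.coexpr_network <- function(object, ...) {
  deg <- igraph::degree(object$graph)
  deg <- deg[deg > 0]
  ggplot2::ggplot(tibble(degree = deg), ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Degree", y = "Nodes",
                  title = sprintf("%s degree distribution", object$method_tag)) +
    ggplot2::theme_minimal()
}
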