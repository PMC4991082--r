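#' Configuration for the JTK-style rhythm scan
#'
#' @param candidate_periods_h Candidate periods in hours. The default (`NULL`)
#'   takes every multiple of the sampling interval that falls inside
#'   `period_window_h`; at 4 h sampling with the default 22--26 h window this
#'   is the single period 24 h. The discrete cosine orderings are only
#'   distinct on that grid, which is why off-grid periods are not scanned.
#' @param phase_step_h Phase grid step in hours (default: the sampling
#'   interval). Tied optimal phases are averaged, so the effective phase
#'   resolution is half the step.
#' @param q_threshold Benjamini-Hochberg q-value cutoff used by
#'   [classify_rhythmic()] (default 0.1).
#' @param period_window_h Period window in hours genes must fall in to be
#'   called rhythmic (default `c(22, 26)`; relax to e.g. `c(20, 28)` for a
#'   wider scan).
#' @param null `"exact"` (convolution over the reference tie structure,
#'   default) or `"permutation"` (Monte Carlo fallback for heavily tied data).
#' @param n_perm Number of permutations when `null = "permutation"`.
#' @param perm_seed Seed for the permutation null.
#' @return A `jtk_config` list.
#' @export
jtk_config <- function(candidate_periods_h = NULL,
                       phase_step_h = NULL,
                       q_threshold = 0.1,
                       period_window_h = c(22, 26),
                       null = c("exact", "permutation"),
                       n_perm = 10000,
                       perm_seed = 1L) {
  null <- match.arg(null)
  if (!is.null(candidate_periods_h) && any(candidate_periods_h <= 0)) {
    abort("candidate periods must be positive")
  }
  structure(list(
    candidate_periods_h = candidate_periods_h,
    phase_step_h = phase_step_h,
    q_threshold = q_threshold,
    period_window_h = period_window_h,
    null = null, n_perm = n_perm, perm_seed = as.integer(perm_seed)
  ), class = "jtk_config")
}

#' Cosine-derived reference ordering
#'
#' Tied ranks of `cos(2*pi*(t - phase)/period)` at the sample times. Samples
#' whose cosine values coincide (replicates at one timepoint, or times placed
#' symmetrically around a peak) share a tie group.
#'
#' @param times Sample times in hours.
#' @param period Period in hours (> 0).
#' @param phase Peak phase in hours.
#' @return Numeric vector of tied ranks, one per sample.
#' @export
jtk_reference_ordering <- function(times, period, phase) {
  if (length(times) == 0) abort("`times` must be non-empty")
  if (period <= 0) abort("`period` must be positive")
  v <- round(cos(2 * pi * (times - phase) / period), 9)
  rank(v, ties.method = "average")
}

#' Jonckheere-Terpstra-Kendall statistic
#'
#' `S` = number of concordant minus discordant pairs between `y` and the
#' reference ordering, over pairs untied in the reference; pairs tied in `y`
#' contribute zero.
#'
#' @param y Numeric data vector.
#' @param ref Reference tied-rank vector (same length).
#' @return Integer-valued S.
#' @export
jt_statistic <- function(y, ref) {
  if (length(y) != length(ref)) abort("`y` and `ref` must have equal lengths")
  ij <- pair_index(length(y))
  sum(sign(ref[ij$j] - ref[ij$i]) * sign(y[ij$j] - y[ij$i]))
}

pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

# ---- exact null distribution ------------------------------------------------

# Mann-Whitney U count polynomial = Gaussian binomial [m+n choose n]_q,
# computed by interleaved exact polynomial multiplication/division; all
# coefficients are integers below 2^53 for the sample sizes handled here.
mwu_counts <- function(m, n) {
  if (m == 0 || n == 0) return(1)
  p <- 1
  for (i in seq_len(n)) {
    # multiply by (1 - q^(m+i))
    d <- m + i
    p2 <- c(p, numeric(d))
    p2[(d + 1):(d + length(p))] <- p2[(d + 1):(d + length(p))] - p
    # divide by (1 - q^i): r[k] = p2[k] + r[k-i]
    r <- p2
    if (length(r) > i) {
      for (k in (i + 1):length(r)) r[k] <- r[k] + r[k - i]
    }
    nz <- which(r != 0)
    p <- r[seq_len(max(nz))]
  }
  p
}

jtk_null_cache <- new.env(parent = emptyenv())

#' Exact null distribution of the JT statistic
#'
#' Distribution of S under exchangeability of a continuous data vector against
#' a tied reference ordering, obtained by convolving Mann-Whitney count
#' polynomials over the reference tie groups (the generating function is the
#' Gaussian multinomial coefficient, so only the multiset of tie-group sizes
#' matters).
#'
#' @param ref Reference tied-rank vector.
#' @return A list of class `jtk_null` with elements `s` (attainable S values),
#'   `prob` (their probabilities), `w_max` (maximum S) and `tail_abs`
#'   (vector with `tail_abs[k + 1]` = P(|S| >= k)).
#' @export
jtk_null_distribution <- function(ref) {
  sizes <- sort(as.integer(table(ref)))
  key <- paste(sizes, collapse = ",")
  hit <- jtk_null_cache[[key]]
  if (!is.null(hit)) return(hit)

  w_max <- (sum(sizes)^2 - sum(sizes^2)) / 2
  pmf <- 1
  m_cum <- 0
  for (n_i in sizes) {
    cnt <- mwu_counts(m_cum, n_i)
    u_pmf <- cnt / sum(cnt)
    pmf <- if (length(pmf) == 1 && length(u_pmf) == 1) 1 else
      conv_open(pmf, u_pmf)
    m_cum <- m_cum + n_i
  }
  w <- seq_along(pmf) - 1
  s <- 2 * w - w_max
  acc <- numeric(w_max + 1)
  a <- abs(s)
  for (k in seq_along(pmf)) acc[a[k] + 1] <- acc[a[k] + 1] + pmf[k]
  tail_abs <- rev(cumsum(rev(acc)))
  out <- structure(list(s = s, prob = pmf, w_max = w_max, tail_abs = tail_abs),
                   class = "jtk_null")
  jtk_null_cache[[key]] <- out
  out
}

conv_open <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (k in seq_along(b)) {
    idx <- k:(k + length(a) - 1)
    out[idx] <- out[idx] + a * b[k]
  }
  out
}

# two-sided exact p for an observed S against a jtk_null
jtk_null_p <- function(null, s_obs) {
  s <- pmin(abs(s_obs), null$w_max)
  null$tail_abs[s + 1]
}

# Monte Carlo null tail for heavily tied data; same interface as the exact one
jtk_perm_null <- function(ref, n_perm, seed) {
  sizes <- sort(as.integer(table(ref)))
  key <- paste("perm", n_perm, seed, paste(sizes, collapse = ","))
  hit <- jtk_null_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(ref)
  ij <- pair_index(n)
  sgn_ref <- sign(ref[ij$j] - ref[ij$i])
  w_max <- sum(sgn_ref != 0)
  s_null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      y <- sample.int(n)
      sum(sgn_ref * sign(y[ij$j] - y[ij$i]))
    }, 1)
  })
  acc <- tabulate(abs(s_null) + 1, nbins = w_max + 1)
  tail_counts <- rev(cumsum(rev(acc)))
  out <- structure(list(tail_counts = tail_counts, n_perm = n_perm,
                        w_max = w_max), class = "jtk_perm_null")
  jtk_null_cache[[key]] <- out
  out
}

jtk_perm_p <- function(null, s_obs) {
  s <- pmin(abs(s_obs), null$w_max)
  (1 + null$tail_counts[s + 1]) / (1 + null$n_perm)
}

# ---- the scan ---------------------------------------------------------------

jtk_period_grid <- function(times, cfg) {
  ut <- sort(unique(times))
  if (length(ut) < 2) abort("need at least 2 distinct timepoints")
  d <- min(diff(ut))
  step <- cfg$phase_step_h %||% d
  periods <- cfg$candidate_periods_h
  if (is.null(periods)) {
    lo <- ceiling(cfg$period_window_h[1] / d)
    hi <- floor(cfg$period_window_h[2] / d)
    if (hi < lo) abort("no candidate period on the sampling grid falls in the period window")
    periods <- d * (lo:hi)
  }
  list(periods = periods, step = step)
}

#' Scan genes for rhythmicity with the JTK test
#'
#' For every gene and every (period, phase) combination on the grid, computes
#' the JT statistic of the gene's expression against the cosine-derived
#' reference ordering and its two-sided exact p-value, then reports the
#' minimizing combination per gene. Because `|S|` is identical for an
#' ordering and its reversal, a phase and its antiphase form one two-sided
#' test; the per-gene minimum p is Bonferroni-multiplied by the number of
#' distinct tests (so it remains a valid p-value), and FDR is then controlled
#' across genes with Benjamini-Hochberg q-values. Tied optimal phases are
#' averaged circularly, and an anti-phase optimum (negative S) is mapped to
#' `phase + period/2`.
#'
#' @param x Expression tibble (replicate-level samples).
#' @param config A [jtk_config()].
#' @return A tibble of class `rhythm_result` with columns `gene_id`,
#'   `p_value`, `q_value`, `period_h`, `phase_zt`, `tau`, `fold_change`
#'   (max/min of raw-scale timepoint means) and `amplitude_log2` (half
#'   peak-to-trough on the log2 scale).
#' @export
jtk_detect <- function(x, config = jtk_config()) {
  info <- sample_info(x)
  m <- expr_matrix(x)
  times <- info$zt
  grid <- jtk_period_grid(times, config)

  combos <- purrr::map(grid$periods, function(p) {
    tibble(period = p, phase = seq(0, p - grid$step, by = grid$step))
  }) %>% bind_rows()

  ij <- pair_index(length(times))
  refs <- purrr::map2(combos$period, combos$phase, function(p, ph) {
    jtk_reference_ordering(times, p, ph)
  })
  # an ordering and its reversal give the same |S|, so a phase and its
  # antiphase are one two-sided test; drop duplicates (the sign of S
  # disambiguates the phase downstream) so the Bonferroni factor below counts
  # distinct tests only
  keys <- vapply(refs, function(r) {
    k1 <- paste(r, collapse = ",")
    k2 <- paste(length(r) + 1 - r, collapse = ",")
    min(k1, k2)
  }, character(1))
  keep <- !duplicated(keys)
  combos <- combos[keep, ]
  refs <- refs[keep]
  n_distinct_tests <- length(refs)
  sgn_ref <- vapply(refs, function(r) sign(r[ij$j] - r[ij$i]),
                    numeric(length(ij$i)))
  n0_ref <- colSums(sgn_ref != 0)

  sgn_y <- sign(m[, ij$j, drop = FALSE] - m[, ij$i, drop = FALSE])
  s_mat <- sgn_y %*% sgn_ref                      # genes x combos
  n0_y <- rowSums(sgn_y != 0)

  p_mat <- matrix(NA_real_, nrow(s_mat), ncol(s_mat))
  for (k in seq_len(ncol(s_mat))) {
    if (config$null == "exact") {
      null_k <- jtk_null_distribution(refs[[k]])
      p_mat[, k] <- jtk_null_p(null_k, s_mat[, k])
    } else {
      null_k <- jtk_perm_null(refs[[k]], config$n_perm, config$perm_seed)
      p_mat[, k] <- jtk_perm_p(null_k, s_mat[, k])
    }
  }

  n_genes <- nrow(m)
  best <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    pv <- p_mat[g, ]
    p_min <- min(pv)
    cand <- which(pv <= p_min * (1 + 1e-9))
    s_abs <- abs(s_mat[g, cand])
    cand <- cand[s_abs >= max(s_abs) - 1e-9]
    per <- min(combos$period[cand])
    cand <- cand[combos$period[cand] == per]
    ph_adj <- ifelse(s_mat[g, cand] >= 0, combos$phase[cand],
                     combos$phase[cand] + per / 2) %% per
    s_best <- max(abs(s_mat[g, cand]))
    denom <- sqrt(max(n0_ref[cand]) * n0_y[g])
    best[[g]] <- c(p = min(1, unname(p_min) * n_distinct_tests), period = per,
                   phase = circular_mean(ph_adj, per),
                   tau = if (denom > 0) unname(s_best / denom) else 0)
  }
  bm <- do.call(rbind, best)

  # fold change / amplitude from raw-scale timepoint means
  zts <- sort(unique(times))
  tp_means <- vapply(zts, function(z) {
    rowMeans(m[, info$sample[info$zt == z], drop = FALSE])
  }, numeric(n_genes))
  if (n_genes == 1) tp_means <- matrix(tp_means, nrow = 1)
  mx <- apply(tp_means, 1, max)
  mn <- apply(tp_means, 1, min)
  fold <- ifelse(mn > 0, mx / mn, NA_real_)

  out <- tibble(
    gene_id = rownames(m),
    p_value = unname(bm[, "p"]),
    q_value = unname(bh_adjust(bm[, "p"])),
    period_h = unname(bm[, "period"]),
    phase_zt = unname(bm[, "phase"]),
    tau = unname(bm[, "tau"]),
    fold_change = fold,
    amplitude_log2 = ifelse(is.na(fold), NA_real_, log2(fold) / 2)
  )
  class(out) <- c("rhythm_result", class(out))
  attr(out, "config") <- config
  out
}

#' @rdname jtk_detect
#' @param y Numeric series for a single gene.
#' @param times Sample times in hours, parallel to `y`.
#' @export
jtk_scan <- function(y, times, config = jtk_config()) {
  labels <- format_zt_label(times, stats::ave(times, times, FUN = seq_along))
  x <- tibble(gene_id = "gene") %>%
    dplyr::bind_cols(as_tibble(setNames(as.list(y), labels)))
  jtk_detect(x, config)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values via [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values (same order as `p`).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call rhythmic genes from a scan result
#'
#' Genes with `q_value` below the threshold and best period inside the period
#' window.
#'
#' @param results A `rhythm_result` tibble from [jtk_detect()].
#' @param q_threshold q-value cutoff (default 0.1).
#' @param period_window_h Inclusive period window in hours (default 22--26).
#' @return Character vector of rhythmic gene ids.
#' @export
classify_rhythmic <- function(results, q_threshold = 0.1,
                              period_window_h = c(22, 26)) {
  keep <- results$q_value < q_threshold &
    results$period_h >= period_window_h[1] &
    results$period_h <= period_window_h[2]
  results$gene_id[keep]
}
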