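#' Single-harmonic cosinor fit
#'
#' Least-squares fit of `y = mesor + a*cos(2*pi*t/T) + b*sin(2*pi*t/T)`.
#' Amplitude is `sqrt(a^2 + b^2)`, the acrophase (time of fitted peak, in ZT
#' hours) comes from `atan2(b, a)`, and the p-value is the F-test of the
#' harmonic terms against the intercept-only model.
#'
#' @param y Numeric series (>= 4 samples).
#' @param times Sample times in hours.
#' @param period Period in hours (default 24).
#' @return An object of class `cosinor_fit`; see [tidy.cosinor_fit()] and
#'   [glance.cosinor_fit()].
#' @export
cosinor_fit <- function(y, times, period = 24) {
  if (length(y) != length(times)) abort("`y` and `times` must have equal lengths")
  if (length(y) < 4) abort("cosinor fit needs at least 4 samples")
  if (length(unique(times)) < 3) abort("singular design: need >= 3 distinct times")
  cw <- cos(2 * pi * times / period)
  sw <- sin(2 * pi * times / period)
  fit <- lm(y ~ cw + sw)
  cf <- coef(fit)
  a <- unname(cf["cw"]); b <- unname(cf["sw"])
  amplitude <- sqrt(a^2 + b^2)
  # y peaks where cos(2 pi t/T - acr) is maximal with acr = atan2(b, a)
  acrophase <- (atan2(b, a) * period / (2 * pi)) %% period
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  df1 <- 2
  df2 <- length(y) - 3
  if (rss1 < .Machine$double.eps * max(1, rss0) && rss0 > 0) {
    f_stat <- Inf; p <- 0
  } else if (rss0 <= .Machine$double.eps) {
    f_stat <- NA_real_; p <- 1     # constant series: no rhythm to test
  } else {
    f_stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  r2 <- if (rss0 > 0) 1 - rss1 / rss0 else 0
  structure(list(
    lm = fit, mesor = unname(cf[1]), amplitude = amplitude,
    acrophase_zt = acrophase, r_squared = max(0, min(1, r2)),
    f_statistic = f_stat, p_value = p, period = period, n = length(y)
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (period %g h): mesor %.4g, amplitude %.4g, acrophase ZT %.2f\n",
    x$period, x$mesor, x$amplitude, x$acrophase_zt))
  cat(sprintf("R^2 = %.3f, F = %.3g, p = %.3g (n = %d)\n",
              x$r_squared, x$f_statistic, x$p_value, x$n))
  invisible(x)
}

#' Tidy a cosinor fit
#'
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per model term with estimate, standard error,
#'   t statistic and p-value. `glance()`: a one-row tibble with the derived
#'   rhythm parameters and overall fit statistics.
#' @method tidy cosinor_fit
#' @export
tidy.cosinor_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble(
    term = c("mesor", "cos", "sin"),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidy.cosinor_fit
#' @method glance cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble(
    mesor = x$mesor, amplitude = x$amplitude, acrophase_zt = x$acrophase_zt,
    r.squared = x$r_squared, statistic = x$f_statistic, p.value = x$p_value,
    period_h = x$period, nobs = x$n
  )
}

#' Summaries of a rhythmic gene set
#'
#' Median peak-to-trough fold change and binned peak-phase counts over the
#' classified rhythmic genes.
#'
#' @param results A `rhythm_result` tibble.
#' @param rhythmic_genes Gene ids to summarise (default: all rows).
#' @param phase_bin_h Phase histogram bin width in hours (default: 4, the
#'   sampling interval of the emulated design).
#' @return A list with `median_fold_change`, `phase_histogram` (tibble of
#'   `bin_start_zt`, `count`) and `fold_changes` (sorted vector).
#' @export
rhythm_summary <- function(results, rhythmic_genes = NULL, phase_bin_h = 4) {
  sub <- if (is.null(rhythmic_genes)) results else
    results[results$gene_id %in% rhythmic_genes, ]
  if (nrow(sub) == 0) abort("no genes to summarise")
  period <- max(sub$period_h)
  breaks <- seq(0, period, by = phase_bin_h)
  bins <- cut(sub$phase_zt %% period, breaks = breaks, right = FALSE,
              include.lowest = TRUE)
  counts <- as.integer(table(bins))
  list(
    median_fold_change = median(sub$fold_change, na.rm = TRUE),
    phase_histogram = tibble(bin_start_zt = breaks[-length(breaks)],
                             count = counts),
    fold_changes = sort(sub$fold_change)
  )
}
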