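#' Configuration for the synthetic diel expression generator
#'
#' Builds the parameter set for [simulate_expression()]. Defaults emulate a
#' light:dark microarray time course: 12 timepoints every 4 h over 44 h, 4
#' technical replicates per timepoint, cosine-shaped rhythmic genes whose peak
#' phases follow a balanced two-mode circular (von Mises) mixture at mid-day
#' (ZT 6) and mid-night (ZT 18), a median peak-to-trough fold change of 2.06,
#' and a raw-fluorescence background floor at 136.5 units.
#'
#' Rhythmic genes are organised into phase-coherent co-expression modules
#' (member phases within +/- 2 h of the module centre); non-rhythmic genes are
#' flat with independent noise. `frac_near_rhythmic` optionally plants
#' module-aligned genes with sub-threshold amplitude (`near_rhythmic_fold`),
#' the kind of gene a network analysis can recover when a per-gene rhythm scan
#' misses it.
#'
#' @param n_genes Number of genes.
#' @param frac_rhythmic Fraction of genes given a full-amplitude rhythm.
#' @param n_modules Number of co-expression modules among rhythmic genes.
#' @param timepoints_h Sampling times in hours (strictly increasing).
#' @param n_replicates Technical replicates per timepoint.
#' @param period_h Rhythm period in hours.
#' @param phase_modes Two mode locations (ZT hours) of the phase mixture.
#' @param phase_kappa Von Mises concentration of each mixture component.
#' @param fold_change_median Median peak-to-trough fold change of rhythmic genes.
#' @param fold_change_spread SD (log2 scale) of fold changes around the median.
#' @param baseline_log2_mean,baseline_log2_sd Baseline intensity distribution
#'   (log2 fluorescence units).
#' @param noise_sd_log2 Per-sample noise SD on the log2 scale.
#' @param module_cor_sd SD (log2 scale) of a per-module, per-sample latent
#'   factor added to every module member. Co-expressed genes share upstream
#'   regulation, so their fluctuations are correlated beyond the common
#'   cosine; this shared variation is what lets a co-expression network
#'   recognise sub-threshold module members that a per-gene scan misses. Set
#'   to 0 for modules whose members are conditionally independent.
#' @param background_floor Raw-scale fluorescence background cutoff.
#' @param frac_below_background Fraction of non-rhythmic genes forced below the
#'   background floor in every sample.
#' @param frac_near_rhythmic Fraction of genes planted as sub-threshold,
#'   module-aligned rhythmic genes (0 disables).
#' @param near_rhythmic_fold Peak-to-trough fold change of sub-threshold genes.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000,
                       frac_rhythmic = 0.08,
                       n_modules = 4,
                       timepoints_h = seq(0, 44, by = 4),
                       n_replicates = 4,
                       period_h = 24,
                       phase_modes = c(6, 18),
                       phase_kappa = 2,
                       fold_change_median = 2.06,
                       fold_change_spread = 0.75,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       noise_sd_log2 = 0.15,
                       module_cor_sd = 0.2,
                       background_floor = 136.5,
                       frac_below_background = 0.10,
                       frac_near_rhythmic = 0,
                       near_rhythmic_fold = 1.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, frac_rhythmic = frac_rhythmic, n_modules = n_modules,
    timepoints_h = timepoints_h, n_replicates = n_replicates,
    period_h = period_h, phase_modes = phase_modes, phase_kappa = phase_kappa,
    fold_change_median = fold_change_median,
    fold_change_spread = fold_change_spread,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_sd_log2 = noise_sd_log2,
    module_cor_sd = module_cor_sd,
    background_floor = background_floor,
    frac_below_background = frac_below_background,
    frac_near_rhythmic = frac_near_rhythmic,
    near_rhythmic_fold = near_rhythmic_fold,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- setdiff(names(cfg), character())
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort(sprintf("sim_config field `%s` must be finite numeric", f))
    }
  }
  if (is.unsorted(cfg$timepoints_h, strictly = TRUE)) {
    abort("timepoints_h must be strictly increasing")
  }
  stopifnot_scalar_number(cfg$frac_rhythmic, "frac_rhythmic", 0, 1)
  stopifnot_scalar_number(cfg$frac_near_rhythmic, "frac_near_rhythmic", 0, 1)
  stopifnot_scalar_number(cfg$frac_below_background, "frac_below_background", 0, 1)
  if (cfg$fold_change_median <= 1) abort("fold_change_median must be > 1")
  if (cfg$n_modules < 1) abort("n_modules must be >= 1")
  if (cfg$period_h <= 0) abort("period_h must be positive")
  n_rhythmic <- round(cfg$frac_rhythmic * cfg$n_genes)
  if (n_rhythmic > 0 && n_rhythmic < cfg$n_modules) {
    abort("frac_rhythmic * n_genes is smaller than n_modules")
  }
  invisible(cfg)
}

# von Mises sampler (Best & Fisher rejection scheme); mu (scalar or length n)
# and result in radians
rvonmises <- function(n, mu, kappa) {
  mu <- rep_len(mu, n)
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f) + mu[i]
        break
      }
    }
  }
  out
}

format_zt_label <- function(t, r) {
  tt <- ifelse(abs(t - round(t)) < 1e-9, sprintf("%02d", as.integer(round(t))),
               format(t, trim = TRUE))
  sprintf("ZT%s_r%d", tt, as.integer(r))
}

#' Simulate a diel expression time course with full ground truth
#'
#' Generates raw-scale fluorescence intensities for `n_genes` genes across the
#' configured time course. Rhythmic genes follow, on the log2 scale,
#' `baseline + (log2(fold)/2) * cos(2*pi*(t - phase)/period)` plus Gaussian
#' noise; they are grouped into phase-coherent modules. Non-rhythmic genes are
#' flat plus noise, and a configurable fraction is forced below the background
#' fluorescence floor so the background filter has work to do.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (wide expression tibble),
#'   `truth` (per-gene tibble: `gene_id`, `is_rhythmic`, `rhythm_class`,
#'   `phase_zt`, `fold_change`, `module_id`) and `modules` (per-module tibble
#'   with the phase centre of each module).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  n <- cfg$n_genes
  n_rhy <- round(cfg$frac_rhythmic * n)
  n_near <- round(cfg$frac_near_rhythmic * n)
  if (n_rhy + n_near > n) abort("rhythmic + near-rhythmic fractions exceed 1")
  gene_ids <- sprintf("g%05d", seq_len(n))

  status <- rep("flat", n)
  idx <- sample.int(n)
  rhy_idx <- idx[seq_len(n_rhy)]
  near_idx <- if (n_near > 0) idx[n_rhy + seq_len(n_near)] else integer()
  status[rhy_idx] <- "rhythmic"
  status[near_idx] <- "subthreshold"
  flat_idx <- which(status == "flat")
  n_below <- round(cfg$frac_below_background * length(flat_idx))
  below_idx <- flat_idx[seq_len(n_below)]
  status[below_idx] <- "below_background"

  # module phase centres from the two-mode circular mixture (modes alternate so
  # the mixture stays balanced across modules)
  n_mod <- if (n_rhy > 0) cfg$n_modules else 0
  modules <- tibble(module_id = character(), phase_center = numeric())
  if (n_mod > 0) {
    mode_of <- cfg$phase_modes[(seq_len(n_mod) - 1) %% length(cfg$phase_modes) + 1]
    centers <- (rvonmises(n_mod, 2 * pi * mode_of / cfg$period_h, cfg$phase_kappa) *
                  cfg$period_h / (2 * pi)) %% cfg$period_h
    modules <- tibble(module_id = sprintf("M%02d", seq_len(n_mod)),
                      phase_center = centers)
  }

  module_id <- rep(NA_character_, n)
  phase <- rep(NA_real_, n)
  fold <- rep(NA_real_, n)

  assign_module <- function(g_idx) {
    if (length(g_idx) == 0 || n_mod == 0) return()
    mod <- rep(seq_len(n_mod), length.out = length(g_idx))
    module_id[g_idx] <<- modules$module_id[mod]
    jit <- pmin(2, pmax(-2, rnorm(length(g_idx), 0, 0.8)))
    phase[g_idx] <<- (modules$phase_center[mod] + jit) %% cfg$period_h
  }
  assign_module(rhy_idx)
  assign_module(near_idx)

  if (n_rhy > 0) {
    f <- cfg$fold_change_median * 2^rnorm(n_rhy, 0, cfg$fold_change_spread)
    fold[rhy_idx] <- pmax(1.2, f)
  }
  if (n_near > 0) {
    fold[near_idx] <- pmax(1.05, cfg$near_rhythmic_fold *
                             2^rnorm(n_near, 0, 0.1))
  }

  tp <- rep(cfg$timepoints_h, each = cfg$n_replicates)
  reps <- rep(seq_len(cfg$n_replicates), times = length(cfg$timepoints_h))
  labels <- format_zt_label(tp, reps)
  n_s <- length(tp)

  baseline <- rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  log2_mat <- matrix(baseline, nrow = n, ncol = n_s)
  has_signal <- !is.na(phase)
  if (any(has_signal)) {
    amp <- log2(fold[has_signal]) / 2
    cosarg <- outer(phase[has_signal], tp, function(p, t) {
      cos(2 * pi * (t - p) / cfg$period_h)
    })
    log2_mat[has_signal, ] <- log2_mat[has_signal, ] + amp * cosarg
  }
  if (n_mod > 0 && cfg$module_cor_sd > 0) {
    factor_mat <- matrix(rnorm(n_mod * n_s, 0, cfg$module_cor_sd), n_mod, n_s)
    mod_index <- match(module_id, modules$module_id)
    in_mod <- which(!is.na(mod_index))
    log2_mat[in_mod, ] <- log2_mat[in_mod, ] + factor_mat[mod_index[in_mod], ]
  }
  log2_mat <- log2_mat + matrix(rnorm(n * n_s, 0, cfg$noise_sd_log2), n, n_s)
  raw <- 2^log2_mat
  if (length(below_idx) > 0) {
    raw[below_idx, ] <- matrix(
      runif(length(below_idx) * n_s, 0.3, 0.95) * cfg$background_floor,
      nrow = length(below_idx)
    )
  }
  colnames(raw) <- labels
  rownames(raw) <- gene_ids

  truth <- tibble(
    gene_id = gene_ids,
    is_rhythmic = status %in% c("rhythmic", "subthreshold"),
    rhythm_class = status,
    phase_zt = phase,
    fold_change = fold,
    module_id = module_id
  )
  list(expression = expr_from_matrix(raw), truth = truth, modules = modules)
}

#' Simulate gene--term annotations aligned with planted modules
#'
#' Each module receives a dedicated term annotating a fixed fraction
#' (`signal`) of its members; the remaining terms are background terms
#' assigned to every gene independently at `noise_rate`. Genes that draw no
#' annotation stay unannotated, playing the role of uncharacterized genes.
#'
#' @param truth Ground-truth tibble from [simulate_expression()].
#' @param n_terms Total number of terms (must be at least the module count).
#' @param signal Fraction of each module annotated with its module term.
#' @param noise_rate Per gene-per-term probability of a background annotation.
#' @param seed Integer seed.
#' @return Annotation tibble (`gene`, `term`) with attribute `module_terms`
#'   mapping module ids to their dedicated terms.
#' @export
simulate_annotations <- function(truth, n_terms, signal = 0.9,
                                 noise_rate = 0.02, seed = 1L) {
  stopifnot_scalar_number(signal, "signal", 0, 1)
  stopifnot_scalar_number(noise_rate, "noise_rate", 0, 1)
  mods <- sort(unique(truth$module_id[!is.na(truth$module_id)]))
  if (n_terms < length(mods)) abort("n_terms must be >= number of modules")
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  module_terms <- tibble(module_id = mods,
                         term = terms[seq_along(mods)])
  bg_terms <- terms[setdiff(seq_len(n_terms), seq_along(mods))]

  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (i in seq_along(mods)) {
      members <- truth$gene_id[!is.na(truth$module_id) &
                                 truth$module_id == mods[i]]
      k <- round(signal * length(members))
      if (k > 0) {
        ann_genes <- sample(members, k)
        rows[[length(rows) + 1]] <- tibble(gene = ann_genes,
                                           term = module_terms$term[i])
      }
    }
    if (noise_rate > 0 && length(bg_terms) > 0) {
      hit <- matrix(runif(nrow(truth) * length(bg_terms)) < noise_rate,
                    nrow = nrow(truth))
      ij <- which(hit, arr.ind = TRUE)
      if (nrow(ij) > 0) {
        rows[[length(rows) + 1]] <- tibble(gene = truth$gene_id[ij[, 1]],
                                           term = bg_terms[ij[, 2]])
      }
    }
    ann <- if (length(rows) > 0) bind_rows(rows) else
      tibble(gene = character(), term = character())
    ann <- distinct(arrange(ann, .data$gene, .data$term))
    attr(ann, "module_terms") <- module_terms
    ann
  })
}

#' Simulate a reference rhythmic-gene list
#'
#' Draws `n` gene ids of which a fraction `1 - contamination` come from truly
#' rhythmic genes and the rest from non-rhythmic genes, emulating an external
#' reference list of known rhythmic genes (e.g. homologs from a related
#' species).
#'
#' @param truth Ground-truth tibble from [simulate_expression()].
#' @param n Number of reference genes.
#' @param contamination Fraction drawn from non-rhythmic genes.
#' @param seed Integer seed.
#' @return Character vector of gene ids.
#' @export
simulate_reference_set <- function(truth, n, contamination = 0, seed = 1L) {
  stopifnot_scalar_number(contamination, "contamination", 0, 1)
  if (n > nrow(truth)) abort("n exceeds the number of genes")
  rhy <- truth$gene_id[truth$is_rhythmic]
  non <- truth$gene_id[!truth$is_rhythmic]
  n_true <- round((1 - contamination) * n)
  if (n_true > length(rhy) || (n - n_true) > length(non)) {
    abort("not enough genes of the requested classes")
  }
  withr::with_seed(as.integer(seed), {
    c(sample(rhy, n_true), sample(non, n - n_true))
  })
}
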