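test_that("simulate_expression is deterministic given the seed", {
  a <- simulate_expression(sim_config(n_genes = 50, seed = 11))
  b <- simulate_expression(sim_config(n_genes = 50, seed = 11))
  expect_identical(a, b)
  c <- simulate_expression(sim_config(n_genes = 50, seed = 12))
  expect_false(identical(a$expression, c$expression))
})

test_that("truth table matches configured fractions", {
  cfg <- sim_config(n_genes = 500, frac_rhythmic = 0.1,
                    frac_near_rhythmic = 0.04, seed = 2)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), 500)
  expect_equal(sum(tr$rhythm_class == "rhythmic"), 50)
  expect_equal(sum(tr$rhythm_class == "subthreshold"), 20)
  expect_equal(sum(tr$is_rhythmic), 70)
  # below-background genes come only from the flat pool
  expect_equal(sum(tr$rhythm_class == "below_background"),
               round(0.10 * (500 - 70)))
  # every rhythmic gene has phase, fold and module
  rhy <- tr[tr$is_rhythmic, ]
  expect_true(all(!is.na(rhy$phase_zt) & !is.na(rhy$fold_change) &
                    !is.na(rhy$module_id)))
  expect_true(all(rhy$phase_zt >= 0 & rhy$phase_zt < 24))
})

test_that("expression table has the right shape and positive values", {
  cfg <- sim_config(n_genes = 30, frac_rhythmic = 0.3,
                    timepoints_h = seq(0, 20, 4),
                    n_replicates = 3, seed = 1)
  sim <- simulate_expression(cfg)
  info <- sample_info(sim$expression)
  expect_equal(nrow(sim$expression), 30)
  expect_equal(nrow(info), 18)
  expect_true(all(as.matrix(sim$expression[info$sample]) > 0))
})

test_that("below-background genes stay below the floor in every sample", {
  sim <- simulate_expression(sim_config(n_genes = 300, seed = 5))
  below <- sim$truth$gene_id[sim$truth$rhythm_class == "below_background"]
  m <- sim$expression[sim$expression$gene_id %in% below, -1]
  expect_true(all(as.matrix(m) < 136.5))
})

test_that("rhythmic genes carry the planted rhythm", {
  cfg <- sim_config(n_genes = 200, noise_sd_log2 = 0.05, module_cor_sd = 0,
                    seed = 3)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  g <- tr$gene_id[tr$rhythm_class == "rhythmic"][1]
  info <- sample_info(sim$expression)
  y <- log2(as.numeric(sim$expression[sim$expression$gene_id == g,
                                      info$sample]))
  fit <- cosinor_fit(y, info$zt, period = 24)
  expect_lt(fit$p_value, 1e-6)
  truth_phase <- tr$phase_zt[tr$gene_id == g]
  expect_lt(abs(dielnet:::circular_diff(fit$acrophase_zt, truth_phase, 24)), 2)
})

test_that("module members are phase-coherent within +/- 2 h", {
  sim <- simulate_expression(sim_config(n_genes = 400, seed = 4))
  tr <- sim$truth[!is.na(sim$truth$module_id), ]
  centers <- sim$modules$phase_center[match(tr$module_id,
                                            sim$modules$module_id)]
  expect_true(all(abs(dielnet:::circular_diff(tr$phase_zt, centers, 24)) <=
                    2 + 1e-9))
})

test_that("config validation rejects bad input", {
  expect_error(sim_config(frac_rhythmic = 1.5), "frac_rhythmic")
  expect_error(sim_config(fold_change_median = 0.9), "fold_change_median")
  expect_error(sim_config(n_genes = 20, frac_rhythmic = 0.1, n_modules = 4),
               "n_modules")
  expect_error(sim_config(timepoints_h = c(4, 0)), "increasing")
})

test_that("simulated annotations align with modules at the set signal", {
  sim <- simulate_expression(sim_config(n_genes = 400, seed = 6))
  ann <- simulate_annotations(sim$truth, n_terms = 10, signal = 1,
                              noise_rate = 0, seed = 1)
  mt <- attr(ann, "module_terms")
  expect_equal(nrow(mt), 4)
  for (i in seq_len(nrow(mt))) {
    members <- sim$truth$gene_id[!is.na(sim$truth$module_id) &
                                   sim$truth$module_id == mt$module_id[i]]
    got <- ann$gene[ann$term == mt$term[i]]
    expect_setequal(got, members)
  }
})

test_that("reference set respects contamination", {
  sim <- simulate_expression(sim_config(n_genes = 400, seed = 6))
  ref <- simulate_reference_set(sim$truth, n = 40, contamination = 0.25,
                                seed = 2)
  rhy <- sim$truth$gene_id[sim$truth$is_rhythmic]
  expect_length(ref, 40)
  expect_equal(sum(ref %in% rhy), 30)
})
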