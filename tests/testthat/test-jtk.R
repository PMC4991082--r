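test_that("reference orderings rank the cosine with ties", {
  # 6 samples over one 24 h cycle, phase 0: cos peaks at t=0, trough at t=12;
  # t=4/20 tie and t=8/16 tie
  r <- jtk_reference_ordering(seq(0, 20, 4), 24, 0)
  expect_equal(r, c(6, 4.5, 2.5, 1, 2.5, 4.5))
  # phase shift moves the peak
  r8 <- jtk_reference_ordering(seq(0, 20, 4), 24, 8)
  expect_equal(which.max(r8), 3)
})

test_that("jt_statistic counts concordant minus discordant pairs", {
  expect_equal(jt_statistic(c(1, 2, 3), c(1, 2, 3)), 3)
  expect_equal(jt_statistic(c(3, 2, 1), c(1, 2, 3)), -3)
  expect_equal(jt_statistic(c(1, 3, 2), c(1, 2, 3)), 1)
  # pairs tied in the reference contribute nothing
  expect_equal(jt_statistic(c(1, 2), c(1, 1)), 0)
  expect_error(jt_statistic(1:3, 1:4), "equal length")
})

test_that("exact null is a probability distribution with correct support", {
  r <- jtk_reference_ordering(seq(0, 44, 4), 24, 0)
  nd <- jtk_null_distribution(r)
  expect_equal(sum(nd$prob), 1, tolerance = 1e-12)
  expect_equal(max(nd$s), nd$w_max)
  expect_equal(min(nd$s), -nd$w_max)
  # symmetric
  expect_equal(nd$prob, rev(nd$prob), tolerance = 1e-12)
  # tail function is the two-sided tail
  expect_equal(dielnet:::jtk_null_p(nd, 0), 1)
  expect_equal(dielnet:::jtk_null_p(nd, nd$w_max), 2 * nd$prob[1],
               tolerance = 1e-12)
})

test_that("exact null depends only on the tie-size multiset", {
  n1 <- jtk_null_distribution(c(1, 2.5, 2.5, 4))
  n2 <- jtk_null_distribution(c(4, 1, 2.5, 2.5))
  expect_equal(n1$prob, n2$prob)
})

test_that("exact null matches exhaustive permutations (tied reference)", {
  ref <- c(1, 2.5, 2.5, 4, 5)   # one tie pair among 5
  nd <- jtk_null_distribution(ref)
  idx <- as.matrix(expand.grid(rep(list(1:5), 5)))
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 5), ]
  s_all <- apply(idx, 1, function(p) jt_statistic(p, ref))
  for (s in 0:max(abs(s_all))) {
    expect_equal(dielnet:::jtk_null_p(nd, s), mean(abs(s_all) >= s),
                 tolerance = 1e-12)
  }
})

test_that("permutation null approximates the exact null", {
  ref <- jtk_reference_ordering(seq(0, 20, 4), 24, 0)
  nd <- jtk_null_distribution(ref)
  pn <- dielnet:::jtk_perm_null(ref, n_perm = 20000, seed = 1)
  for (s in c(3, 7, 11)) {
    expect_equal(dielnet:::jtk_perm_p(pn, s), dielnet:::jtk_null_p(nd, s),
                 tolerance = 0.02)
  }
})

test_that("jtk_scan finds a clean rhythm with the right phase and period", {
  times <- rep(seq(0, 44, 4), each = 2)
  y <- 2^(10 + 0.5 * cos(2 * pi * (times - 8) / 24))
  res <- jtk_scan(y, times)
  expect_equal(res$period_h, 24)
  expect_equal(res$phase_zt, 8)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$tau, 1)
})

test_that("phase grid averaging recovers off-grid phases", {
  # true phase 6 sits between grid phases 4 and 8; tie-averaging must yield 6
  # (rounded so symmetric samples are exact ties, not 1e-16 apart)
  times <- seq(0, 44, 4)
  y <- round(cos(2 * pi * (times - 6) / 24), 9)
  res <- jtk_scan(y, times)
  expect_equal(res$phase_zt, 6)
})

test_that("anti-phase optima map to phase + period/2", {
  times <- seq(0, 44, 4)
  y <- -cos(2 * pi * times / 24)    # trough at 0 = peak at 12
  res <- jtk_scan(y, times)
  expect_equal(res$phase_zt, 12)
})

test_that("fold change uses raw timepoint means", {
  x <- tibble::tibble(gene_id = "g",
                      ZT00_r1 = 90, ZT00_r2 = 110,
                      ZT12_r1 = 390, ZT12_r2 = 410)
  cfg <- jtk_config(candidate_periods_h = 24, phase_step_h = 12,
                    period_window_h = c(22, 26))
  res <- jtk_detect(x, cfg)
  expect_equal(res$fold_change, 4)      # 400 / 100
  expect_equal(res$amplitude_log2, 1)   # log2(4)/2
})

test_that("per-ordering null p-values are uniform on permuted data", {
  # validity check for a single reference ordering: exact p of a random
  # permutation is super-uniform at every threshold
  ref <- jtk_reference_ordering(seq(0, 44, 4), 24, 0)
  nd <- jtk_null_distribution(ref)
  withr::with_seed(42, {
    p <- replicate(2000, {
      dielnet:::jtk_null_p(nd, jt_statistic(sample(12), ref))
    })
  })
  for (a in c(0.01, 0.05, 0.2, 0.5)) {
    expect_lt(mean(p <= a), a + 3 * sqrt(a * (1 - a) / 2000))
  }
})

test_that("scan p-values on pure noise are valid after the grid correction", {
  sim <- simulate_expression(sim_config(n_genes = 400, frac_rhythmic = 0,
                                        frac_below_background = 0, seed = 9))
  res <- jtk_detect(sim$expression)
  for (a in c(0.01, 0.05, 0.2)) {
    expect_lt(mean(res$p_value <= a), a + 3 * sqrt(a * (1 - a) / 400))
  }
  expect_length(classify_rhythmic(res, 0.1), 0)
})

test_that("bh_adjust matches p.adjust and validates input", {
  p <- c(0.01, 0.02, 0.5, 1)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "0, 1")
})

test_that("classify_rhythmic applies q and period windows", {
  res <- tibble::tibble(gene_id = c("a", "b", "c"),
                        q_value = c(0.05, 0.05, 0.2),
                        period_h = c(24, 20, 24))
  expect_equal(classify_rhythmic(res, 0.1, c(22, 26)), "a")
})

test_that("permutation-null scan agrees with the exact scan on clean data", {
  times <- rep(seq(0, 20, 4), each = 2)
  withr::with_seed(8, {
    y <- 2^(8 + 0.6 * cos(2 * pi * (times - 4) / 24) + rnorm(12, 0, 0.1))
  })
  ex <- jtk_scan(y, times)
  pm <- jtk_scan(y, times, jtk_config(null = "permutation", n_perm = 5000))
  expect_equal(pm$period_h, ex$period_h)
  expect_equal(pm$phase_zt, ex$phase_zt)
  expect_equal(pm$tau, ex$tau)
})
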