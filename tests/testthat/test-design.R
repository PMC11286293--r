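test_that("depth thinning follows f = d_target / d_original, capped at 1", {
  fx <- single_cross_cohort(n_f2 = 6, n_sites = 10000, depth = 0, seed = 1)
  coh <- fx$cohort
  # deterministic read counts so the original depth is exact
  coh$ref_count[] <- 1L
  coh$alt_count[] <- 0L
  coh$ref_count[!coh$samples$is_truth, 1:4000] <- 2L  # 1.4x for F2 samples
  d0 <- realized_depth(coh)
  f2 <- which(!coh$samples$is_truth)
  expect_equal(unname(d0[f2]), rep(1.4, length(f2)))

  thin <- downsample_depth(coh, 0.5, seed = 2)
  kept <- realized_depth(thin)
  f <- 0.5 / 1.4
  tot <- 1.4 * 10000
  sd3 <- 3 * sqrt(tot * f * (1 - f)) / 10000
  expect_true(all(abs(kept[f2] - 0.5) < sd3))
  # truth samples follow the cohort's target depth
  expect_true(all(kept[coh$samples$is_truth] < 1))

  # samples already below the target are untouched
  low <- coh
  low$ref_count[f2, ] <- rbinom(length(low$ref_count[f2, ]), 1, 0.3)
  thin2 <- downsample_depth(low, 0.5, seed = 3)
  expect_identical(thin2$ref_count[f2, ], low$ref_count[f2, ])

  # site set and flags preserved
  expect_identical(thin$samples$is_truth, coh$samples$is_truth)
  expect_identical(dim(thin$ref_count), dim(coh$ref_count))
  expect_error(downsample_depth(coh, -1), "positive")
})

test_that("sample downsampling always retains the truth samples", {
  fx <- single_cross_cohort(n_f2 = 47, n_sites = 50, depth = 1, seed = 4)
  coh <- fx$cohort  # 47 F2 + 3 truth
  n_truth <- sum(coh$samples$is_truth)

  expect_equal(downsample_samples(coh, nrow(coh$samples), seed = 1), coh)
  only_truth <- downsample_samples(coh, n_truth, seed = 1)
  expect_true(all(only_truth$samples$is_truth))

  sub <- downsample_samples(coh, 20, seed = 5)
  expect_equal(nrow(sub$samples), 20)
  expect_equal(sum(sub$samples$is_truth), n_truth)

  expect_error(downsample_samples(coh, n_truth - 1), "truth")
  expect_error(downsample_samples(coh, 1000), "larger")
})

test_that("cross removal reproduces the reference bookkeeping sequence", {
  des <- medaka_cross_design()
  steps <- downsample_crosses(des)$steps
  expect_equal(steps$n_lines, c(8, 7, 6, 5, 4, 3, 2))
  expect_equal(steps$n_crosses, c(10, 9, 7, 6, 4, 3, 1))
  final <- downsample_crosses(des)$designs[[7]]
  expect_equal(final$crosses$sire, "72-2")
  expect_equal(final$crosses$dam, "55-2")

  expect_error(downsample_crosses(des, "zz-9"), "unknown")
  expect_equal(downsample_crosses(des, character(0))$steps$n_crosses, 10)
})

test_that("cross removal drops all member samples, truth included", {
  des <- medaka_cross_design(scale = 0.02)
  map <- make_genome_map(1, 1e6, 30, 2, seed = 6)
  panel <- simulate_founders(map, 8, 0.01, seed = 7,
                             line_ids = design_summary(des)$lines)
  coh <- simulate_cross(panel, des, map, seed = 8)
  out <- downsample_crosses(des, cohort = coh)
  for (s in seq_along(out$cohorts)) {
    ids <- out$designs[[s]]$crosses$id
    expect_true(all(out$cohorts[[s]]$samples$cross %in% ids))
  }
  # the last step keeps a single cross's samples including its truth F1
  last <- out$cohorts[[7]]
  expect_true(all(last$samples$cross == "72-2x55-2"))
})

test_that("K follows twice the number of founder lines", {
  expect_equal(choose_k(8), 16L)
  expect_equal(choose_k(2), 4L)
  expect_equal(choose_k(1), 2L)
  expect_error(choose_k(0))
})

test_that("the cost model evaluates its formula exactly", {
  cp <- cost_params()
  expect_equal(cost(0, 1.4, cp), 0)
  expect_equal(cost(10, 0, cp), 10)
  expect_equal(cost(1, 1.4, cp),
               1.4 * 734040372 / 273542732637 * 683.89 + 1)
  expect_equal(cost(1, 1.4, cp), 3.5693, tolerance = 1e-4)

  expect_equal(relative_cost(100, 1.4, 100, 1.4, cp), 1.0)
  expect_equal(relative_cost(2177, 0.5, 2177, 1.4, cp), 0.537,
               tolerance = 5e-4)
  expect_equal(relative_cost(50, 0.9, 100, 0.9, cp), 0.5)
  expect_error(relative_cost(1, 1, 0, 0, cp), "positive")
})

test_that("relative cost is independent of n when n equals the reference", {
  set.seed(9)
  for (i in 1:20) {
    cp <- cost_params(g = runif(1, 1e8, 1e9),
                      flowcell_output = runif(1, 1e11, 1e12),
                      cf = runif(1, 100, 1000), cp = runif(1, 0.5, 2))
    d <- runif(1, 0.1, 2); d_ref <- runif(1, 0.1, 2)
    r <- vapply(c(10, 500, 2177), function(n)
      relative_cost(n, d, n, d_ref, cp), numeric(1))
    expect_lt(max(abs(r - r[1])), 1e-12)
  }
})

test_that("a degenerate sweep equals a direct imputation run", {
  fx <- single_cross_cohort(n_f2 = 30, n_sites = 200, depth = 1, seed = 10)
  p <- hmm_params(K = 4, n_iterations = 15, seed = 1)
  sw <- sweep_design(fx$cohort, fx$map, n_grid = nrow(fx$cohort$samples),
                     depth_grid = NA, params = p, replicates = 1, seed = 3)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$relative_cost, 1.0)

  # replicate the sweep's seed derivation by hand
  run_seed <- as.integer(3 + 1009L + 101L)
  sub <- downsample_samples(fx$cohort, nrow(fx$cohort$samples),
                            seed = run_seed)
  sub <- downsample_depth(sub, NULL, seed = run_seed + 1L)
  p2 <- p; p2$seed <- run_seed
  fit <- run_em(sub, fx$map, p2)
  ti <- which(sub$samples$is_truth)
  direct <- per_sample_concordance(fit$dosage[ti, , drop = FALSE],
                                   sub$truth_geno[ti, , drop = FALSE])
  expect_equal(sw$mean_r2, direct$mean_r2)
})
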