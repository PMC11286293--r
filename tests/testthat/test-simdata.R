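test_that("genome maps are sorted, in range and seed-reproducible", {
  map <- make_genome_map(2, 5e6, 500, exp_rate = 2, seed = 1)
  expect_equal(nrow(map$sites), 1000)
  for (ch in map$chromosomes$name) {
    pos <- map$sites$pos[map$sites$chrom == ch]
    expect_true(all(diff(pos) > 0))
    expect_true(min(pos) >= 1 && max(pos) <= 5e6)
  }
  expect_identical(map, make_genome_map(2, 5e6, 500, exp_rate = 2, seed = 1))
  expect_false(identical(map$sites,
                         make_genome_map(2, 5e6, 500, 2, seed = 2)$sites))
  expect_error(make_genome_map(1, 100, 200, 2, seed = 1), "more sites")
})

test_that("founder panels respect residual heterozygosity and polymorphism", {
  map <- make_genome_map(1, 5e6, 2000, 2, seed = 3)
  hom <- simulate_founders(map, 8, residual_het = 0, seed = 4)
  expect_true(all(hom$hap_a == hom$hap_b))

  het <- simulate_founders(map, 8, residual_het = 0.01, seed = 5)
  frac <- mean(het$hap_a != het$hap_b)
  n_pairs <- 8 * 2000
  sd3 <- 3 * sqrt(0.01 * 0.99 / n_pairs)
  expect_lt(abs(frac - 0.01), sd3)

  # every site polymorphic across the panel's 16 haplotypes
  all_h <- rbind(het$hap_a, het$hap_b)
  expect_false(any(apply(all_h, 2, function(x) all(x == x[1]))))
  all_h <- rbind(hom$hap_a, hom$hap_b)
  expect_false(any(apply(all_h, 2, function(x) all(x == x[1]))))

  expect_error(simulate_founders(map, 1), "at least 2")
  expect_error(simulate_founders(map, 4, residual_het = 0.6), "residual_het")
})

test_that("meiosis produces parental mosaics with Poisson crossovers", {
  map <- make_genome_map(1, 5e6, 400, exp_rate = 2, seed = 6)
  h <- rbinom(400, 1, 0.5)
  expect_identical(meiosis(h, h, map, seed = 1), h)

  map0 <- make_genome_map(1, 5e6, 400, exp_rate = 0, seed = 6)
  a <- rep(0L, 400); b <- rep(1L, 400)
  g <- meiosis(a, b, map0, seed = 2)
  expect_true(all(g == 0L) || all(g == 1L))

  # crossover-count oracle: lambda = exp_rate * L_Mb / 100 = 2 * 5 / 100
  set.seed(7)
  switches <- replicate(10000, sum(diff(meiosis(a, b, map)) != 0))
  lambda <- 2 * 5 / 100
  expect_lt(abs(mean(switches) - lambda), 3 * sqrt(lambda / 10000) + 1e-3)
})

test_that("F2 crosses segregate like Mendel and flag the planned truth set", {
  fx <- single_cross_cohort(n_f2 = 400, n_sites = 60, depth = 0, seed = 11)
  cohort <- fx$cohort

  # both lines inbred and every site a fixed difference: F1 all heterozygous
  f1 <- cohort$truth_geno[cohort$samples$generation == "F1", , drop = FALSE]
  expect_true(all(f1 == 1))

  # 1:2:1 segregation among the F2 at an arbitrary site
  f2 <- cohort$truth_geno[cohort$samples$generation == "F2", 30]
  counts <- table(factor(f2, levels = 0:2))
  expect_gt(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.001)

  # F2 allele frequency 0.5 within 3 binomial SD
  af <- colMeans(cohort$truth_geno[cohort$samples$generation == "F2", ]) / 2
  sd3 <- 3 * sqrt(0.5 * 0.5 / (2 * 400))
  expect_true(all(abs(af - 0.5) < sd3))

  expect_error(
    simulate_cross(fx$panel,
                   cross_design(data.frame(sire = "nope", dam = "line_1",
                                           n_f2 = 5)),
                   fx$map),
    "unknown line")
})

test_that("the reference design yields 12 truth samples and 2207 low-coverage F2s", {
  des <- medaka_cross_design()
  map <- make_genome_map(1, 1e6, 40, 2, seed = 12)
  panel <- simulate_founders(map, 8, 0.01, seed = 13,
                             line_ids = design_summary(des)$lines)
  cohort <- simulate_cross(panel, des, map, seed = 14)
  expect_equal(sum(cohort$samples$is_truth), 12)
  expect_equal(sum(cohort$samples$is_truth &
                     cohort$samples$generation == "F1"), 10)
  low <- !cohort$samples$is_truth & cohort$samples$generation == "F2"
  expect_equal(sum(low), 2207)
})

test_that("origin switches along F2 gametes reflect two meioses", {
  map <- make_genome_map(1, 5e6, 500, exp_rate = 8, seed = 15)
  panel <- simulate_founders(map, 2, 0, seed = 16)
  des <- cross_design(data.frame(sire = "line_1", dam = "line_2",
                                 n_f2 = 2000), extra_f2_truth = 0,
                      f1_truth_per_cross = 0)
  cohort <- simulate_cross(panel, des, map, seed = 17, n_f1 = 200,
                           keep_origin = TRUE)
  lambda <- 8 * 5 / 100
  switches <- vapply(cohort$origin, function(o)
    sum(diff(o[1, ]) != 0) + sum(diff(o[2, ]) != 0), numeric(1))
  # each F2 gamete accumulates about two meioses' worth of crossovers
  expect_lt(abs(mean(switches) / 2 - 2 * lambda), 0.1)
})

test_that("read simulation matches its Poisson/error model", {
  fx <- single_cross_cohort(n_f2 = 100, n_sites = 500, depth = 0, seed = 21)
  expect_true(all(fx$cohort$ref_count + fx$cohort$alt_count == 0 |
                    fx$cohort$samples$is_truth))

  # zero error, homozygous alt: no reference reads at covered sites
  coh <- simulate_cross(fx$panel,
                        cross_design(data.frame(sire = "line_1",
                                                dam = "line_1", n_f2 = 10),
                                     extra_f2_truth = 0,
                                     f1_truth_per_cross = 0),
                        fx$map, seed = 22)
  coh$truth_geno[] <- 2L
  coh <- simulate_reads(coh, 1, base_error = 0, seed = 23)
  expect_true(all(coh$ref_count == 0))

  # realized depth near target in fixed-depth mode
  fx2 <- single_cross_cohort(n_f2 = 400, n_sites = 2000, depth = 0, seed = 24)
  coh2 <- simulate_reads(fx2$cohort, 1.0, 0.01, seed = 25, depth_cv = 0)
  f2 <- !coh2$samples$is_truth
  m <- mean(coh2$ref_count[f2, ] + coh2$alt_count[f2, ])
  expect_lt(abs(m - 1.0), 3 * sqrt(1.0 / (400 * 2000)))
})

test_that("cohort simulation is bit-reproducible under a fixed seed", {
  a <- single_cross_cohort(n_f2 = 20, n_sites = 100, depth = 1, seed = 31)
  b <- single_cross_cohort(n_f2 = 20, n_sites = 100, depth = 1, seed = 31)
  expect_identical(a$cohort, b$cohort)
})
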