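test_that("transition schedule follows the Haldane-style closed form", {
  map <- make_genome_map(1, 5e6, 100, 2, seed = 1)
  map$sites$pos <- sort(sample.int(5e6, 100))
  sched <- transition_schedule(map, n_gen = 2, exp_rate = 2)
  d_mb <- diff(map$sites$pos) / 1e6
  expect_equal(sched$rho, 1 - exp(-2 * 2 * d_mb / 100))

  # 1 Mb at nGen = 2, expRate = 2 gives 1 - exp(-0.04)
  map2 <- map
  map2$sites <- data.frame(chrom = "chr1", pos = c(1, 1 + 1e6))
  expect_equal(transition_schedule(map2, 2, 2)$rho, 1 - exp(-0.04))
  expect_equal(1 - exp(-0.04), 0.039211, tolerance = 1e-4)

  # chromosome boundaries reset the chains
  map3 <- make_genome_map(2, 1e6, 50, 2, seed = 2)
  sched3 <- transition_schedule(map3, 2, 2)
  expect_equal(sched3$rho[50], 1)

  # huge distance saturates at 1
  map4 <- map2
  map4$sites$pos <- c(1, 5e9)
  map4$chromosomes$length <- 5e9
  expect_equal(transition_schedule(map4, 2, 2)$rho, 1, tolerance = 1e-12)
})

test_that("emission likelihood is a per-read product", {
  expect_equal(emission_likelihood(0, 0, 0.3, 0.01), 1.0)
  expect_equal(emission_likelihood(0, 1, 1, 0), 1.0)
  expect_equal(emission_likelihood(2, 1, 0.5, 0.01), 0.125)
  expect_equal(emission_likelihood(2, 1, 0.5, 0.3), 0.125)
  # vectorized over sites
  expect_equal(emission_likelihood(c(1, 0), c(0, 2), 0, 0.1),
               c(0.9, 0.01))
})

test_that("forward-backward matches the exhaustive-path oracle", {
  for (seed in 1:30) {
    inst <- random_fb_instance(seed, K = 1 + seed %% 2)
    TT <- nrow(inst$reads)
    fb <- forward_backward_diploid(inst$reads, inst$theta,
                                   list(rho = inst$rho), inst$alpha,
                                   inst$eps)
    oracle <- brute_force_fb(inst$reads, inst$theta, inst$rho, inst$alpha,
                             inst$eps)
    expect_lt(max(abs(fb$posteriors - oracle$posteriors)), 1e-8)
    expect_lt(abs(fb$loglik - oracle$loglik), 1e-8)
  }
})

test_that("degenerate copying chains behave as expected", {
  TT <- 5
  reads <- matrix(rpois(TT * 2, 1), TT, 2)

  # K = 1: a single state everywhere
  theta1 <- matrix(runif(TT), 1, TT)
  fb1 <- forward_backward_diploid(reads, theta1,
                                  list(rho = rep(0.1, TT - 1)), c(1), 0.01)
  expect_equal(as.vector(fb1$posteriors), rep(1, TT))

  # uniform theta = 0.5: all states equiposterior by symmetry
  theta2 <- matrix(0.5, 3, TT)
  fb2 <- forward_backward_diploid(reads, theta2,
                                  list(rho = rep(0.2, TT - 1)), NULL, 0.01)
  expect_equal(as.vector(fb2$posteriors), rep(1 / 9, 9 * TT))

  expect_error(forward_backward_diploid(matrix(0, 0, 2), theta1,
                                        list(rho = numeric(0))), "sites")
  expect_error(forward_backward_diploid(reads, theta2,
                                        list(rho = rep(0.2, TT - 1)),
                                        alpha = c(0.5, 0.2, 0.2)),
               "alpha")
})

test_that("EM updates respond correctly to evidence", {
  # saturated responsibility: all-alt reads, posterior fixed on haplotype 1
  K <- 2; TT <- 2
  theta <- matrix(0.5, K, TT)
  post <- array(0, c(K, K, TT))
  post[1, 1, ] <- 1
  reads <- matrix(c(0, 0, 20, 0), TT, 2)  # site 1: 20 alt reads; site 2: none
  up <- em_update(theta, list(post), list(reads), base_error = 0)
  expect_equal(up$theta[1, 1], 1 - 1e-4)
  # no-evidence site keeps its value
  expect_equal(up$theta[1, 2], 0.5)
  # haplotype without posterior mass keeps its value
  expect_equal(up$theta[2, 1], 0.5)

  # no reads anywhere: theta unchanged
  up0 <- em_update(theta, list(post), list(matrix(0, TT, 2)), 0.01)
  expect_equal(up0$theta, theta)

  # balanced ref/alt evidence on a symmetric model: updates to 0.5
  post_u <- array(0.25, c(K, K, TT))
  reads_b <- matrix(c(1, 1, 1, 1), TT, 2)
  up_b <- em_update(theta, list(post_u), list(reads_b), 0)
  expect_equal(up_b$theta, matrix(0.5, K, TT))
})

test_that("the R EM update agrees with the compiled E-pass accumulator", {
  fx <- single_cross_cohort(n_f2 = 8, n_sites = 15, depth = 2, seed = 41)
  coh <- fx$cohort
  K <- 3; TT <- 15
  set.seed(42)
  theta <- matrix(runif(K * TT, 0.1, 0.9), K, TT)
  alpha <- c(0.5, 0.3, 0.2)
  sched <- transition_schedule(fx$map, 2, 2)
  posts <- list(); reads <- list()
  for (i in seq_len(nrow(coh$samples))) {
    rd <- cbind(coh$ref_count[i, ], coh$alt_count[i, ])
    reads[[i]] <- rd
    posts[[i]] <- forward_backward_diploid(rd, theta, sched, alpha,
                                           0.01)$posteriors
  }
  up <- em_update(theta, posts, reads, 0.01)
  refm <- coh$ref_count; altm <- coh$alt_count
  storage.mode(refm) <- "double"; storage.mode(altm) <- "double"
  pass <- crossimpute:::.em_pass_cpp(refm, altm, theta, sched$rho, alpha,
                                     0.01, FALSE)
  theta_cpp <- ifelse(pass$den > 1e-12, pass$num / pass$den, theta)
  theta_cpp <- pmin(pmax(theta_cpp, 1e-4), 1 - 1e-4)
  expect_equal(up$theta, theta_cpp, tolerance = 1e-10)
  expect_equal(up$alpha, as.vector(pass$usage / sum(pass$usage)),
               tolerance = 1e-10)
})

test_that("run_em is deterministic, normalized and self-consistent", {
  fx <- single_cross_cohort(n_f2 = 30, n_sites = 80, depth = 1, seed = 51)
  p <- hmm_params(K = 4, n_iterations = 10, seed = 7)
  fit1 <- run_em(fx$cohort, fx$map, p)
  fit2 <- run_em(fx$cohort, fx$map, p)
  expect_identical(fit1, fit2)

  gp_sum <- fit1$gp[, , 1] + fit1$gp[, , 2] + fit1$gp[, , 3]
  expect_lt(max(abs(gp_sum - 1)), 1e-8)
  expect_lt(max(abs(fit1$gp[, , 2] + 2 * fit1$gp[, , 3] - fit1$dosage)),
            1e-8)
  expect_true(all(fit1$dosage >= 0 & fit1$dosage <= 2))

  empty <- fx$cohort
  empty$ref_count <- NULL
  expect_error(run_em(empty, fx$map, p), "read counts")
  one_site <- subset_sites(fx$cohort, 1)
  expect_error(run_em(one_site, subset_map(fx$map, 1), p), "sites")
})

test_that("plain EM increases the total log-likelihood monotonically", {
  fx <- single_cross_cohort(n_f2 = 25, n_sites = 60, depth = 1, seed = 61)
  for (mode in c("jump", "usage", "none")) {
    p <- hmm_params(K = 3, n_iterations = 25, seed = 3, alpha_update = mode)
    fit <- run_em(fx$cohort, fx$map, p)
    expect_gt(min(diff(fit$loglik_trace)), -1e-6)
  }
})

test_that("relabelling the ancestral haplotypes leaves dosages unchanged", {
  fx <- single_cross_cohort(n_f2 = 10, n_sites = 40, depth = 1, seed = 71)
  coh <- fx$cohort
  K <- 4; TT <- 40
  set.seed(8)
  theta <- matrix(runif(K * TT, 0.1, 0.9), K, TT)
  alpha <- c(0.4, 0.3, 0.2, 0.1)
  sched <- transition_schedule(fx$map, 2, 2)
  refm <- coh$ref_count; altm <- coh$alt_count
  storage.mode(refm) <- "double"; storage.mode(altm) <- "double"
  perm <- c(3, 1, 4, 2)
  a <- crossimpute:::.em_pass_cpp(refm, altm, theta, sched$rho, alpha,
                                  0.01, TRUE)
  b <- crossimpute:::.em_pass_cpp(refm, altm, theta[perm, ], sched$rho,
                                  alpha[perm], 0.01, TRUE)
  expect_equal(a$dosage, b$dosage, tolerance = 1e-10)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-10)
})

test_that("info score reflects posterior certainty", {
  # all posteriors degenerate at a polymorphic site: full information
  gp <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(info_score(gp), 1.0)

  # monomorphic estimated frequency: undefined
  gp0 <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_true(is.na(info_score(gp0)))

  # three-sample case against the direct formula
  gp3 <- rbind(c(0.9, 0.1, 0), c(0.2, 0.6, 0.2), c(0, 0.3, 0.7))
  ds <- gp3[, 2] + 2 * gp3[, 3]
  v <- gp3[, 2] + 4 * gp3[, 3] - ds^2
  f <- mean(ds) / 2
  expect_equal(info_score(gp3), 1 - mean(v) / (2 * f * (1 - f)))
})
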