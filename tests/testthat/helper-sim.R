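# shared fixtures and independent oracles, built in code at test time

# small single-cross cohort: 2 fully inbred founder lines, every site a
# fixed difference between them
single_cross_cohort <- function(n_f2 = 50, n_sites = 300, depth = 1,
                                seed = 1, residual_het = 0,
                                chrom_len = 5e6, base_error = 0.01,
                                n_lines = 2, n_crosses = 1,
                                f2_per_cross = NULL, n_chrom = 1) {
  map <- make_genome_map(n_chrom, chrom_len, n_sites, 2, seed = seed)
  panel <- simulate_founders(map, n_lines, residual_het, seed = seed + 1)
  if (is.null(f2_per_cross)) f2_per_cross <- n_f2
  sires <- paste0("line_", seq(1, 2 * n_crosses, by = 2))
  dams <- paste0("line_", seq(2, 2 * n_crosses, by = 2))
  des <- cross_design(data.frame(sire = sires, dam = dams,
                                 n_f2 = f2_per_cross))
  cohort <- simulate_cross(panel, des, map, seed = seed + 2)
  cohort <- simulate_reads(cohort, depth, base_error, seed = seed + 3)
  list(map = map, panel = panel, design = des, cohort = cohort)
}

# exhaustive-path oracle for the diploid copying HMM: sums over all
# (K^2)^T state paths, with the same emission model as the package
# (allele copies Bernoulli(theta), read stack depending on their sum)
brute_force_fb <- function(reads, theta, rho, alpha, eps) {
  K <- nrow(theta); TT <- nrow(reads)
  L <- sapply(0:2, function(g)
    emission_likelihood(reads[, 1], reads[, 2], g / 2, eps))
  L <- matrix(L, nrow = TT)
  emis <- function(k1, k2, t) {
    th1 <- theta[k1, t]; th2 <- theta[k2, t]
    (1 - th1) * (1 - th2) * L[t, 1] +
      (th1 * (1 - th2) + (1 - th1) * th2) * L[t, 2] +
      th1 * th2 * L[t, 3]
  }
  trans <- function(k, l, r) (1 - r) * (k == l) + r * alpha[l]
  states <- expand.grid(k1 = seq_len(K), k2 = seq_len(K))
  paths <- expand.grid(rep(list(seq_len(K * K)), TT))
  post <- array(0, c(K, K, TT)); total <- 0
  for (p in seq_len(nrow(paths))) {
    pr <- 1
    for (t in seq_len(TT)) {
      s <- paths[p, t]
      k1 <- states$k1[s]; k2 <- states$k2[s]
      if (t == 1) {
        pr <- pr * alpha[k1] * alpha[k2]
      } else {
        sp <- paths[p, t - 1]
        pr <- pr * trans(states$k1[sp], k1, rho[t - 1]) *
          trans(states$k2[sp], k2, rho[t - 1])
      }
      pr <- pr * emis(k1, k2, t)
    }
    total <- total + pr
    for (t in seq_len(TT)) {
      s <- paths[p, t]
      post[states$k1[s], states$k2[s], t] <-
        post[states$k1[s], states$k2[s], t] + pr
    }
  }
  list(posteriors = post / total, loglik = log(total))
}

# random small HMM instance for oracle comparisons
random_fb_instance <- function(seed, K = 2, TT = NULL) {
  set.seed(seed)
  if (is.null(TT)) TT <- sample(2:4, 1)
  list(theta = matrix(runif(K * TT), K, TT),
       rho = runif(TT - 1),
       alpha = {
         a <- runif(K) + 0.1
         a / sum(a)
       },
       reads = matrix(rpois(TT * 2, 1), TT, 2),
       eps = runif(1, 0, 0.05))
}

# best assignment of the two most-used reconstructed haplotypes to the two
# founder haplotypes, by total absolute error
theta_recovery_mae <- function(fit, panel) {
  top2 <- order(fit$usage, decreasing = TRUE)[1:2]
  h1 <- panel$hap_a[1, ]; h2 <- panel$hap_a[2, ]
  straight <- (mean(abs(fit$theta[top2[1], ] - h1)) +
                 mean(abs(fit$theta[top2[2], ] - h2))) / 2
  crossed <- (mean(abs(fit$theta[top2[1], ] - h2)) +
                mean(abs(fit$theta[top2[2], ] - h1))) / 2
  min(straight, crossed)
}
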