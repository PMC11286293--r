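#' Imputation model hyperparameters
#'
#' Container for the reference-free imputation engine's settings.  The
#' defaults follow the configuration that works well for an F2 cross of
#' inbred lines: two generations since founding and a uniform 2 cM/Mb
#' recombination rate, with `K` left to the caller (see [choose_k()] for
#' the founder-based rule).
#'
#' @param K Number of ancestral haplotypes to reconstruct (>= 1).
#' @param n_gen Generations since founding of the imputed population.
#' @param exp_rate Recombination rate in cM/Mb.
#' @param n_iterations Number of EM iterations.
#' @param seed Integer seed governing the haplotype initialization.
#' @param refill Enable the refill heuristic: twice during the run (at a
#'   quarter and at half of the iterations), haplotypes with mean usage
#'   below `1/(4K)` are re-seeded from the most-used haplotype plus noise.
#'   Off by default because it breaks the monotone-likelihood guarantee of
#'   plain EM.
#' @param tol Relative log-likelihood increase below which the EM loop
#'   stops early; 0 (the default) always runs all `n_iterations`.
#' @param alpha_update How the ancestral haplotype weights are
#'   re-estimated: `"jump"` (exact M-step from expected copying-jump
#'   landings; the default, which preserves EM monotonicity), `"usage"`
#'   (normalized mean marginal usage) or `"none"`.
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(K, n_gen = 2, exp_rate = 2, n_iterations = 100,
                       seed = 1, refill = FALSE, tol = 0,
                       alpha_update = c("jump", "usage", "none")) {
  stopifnot(K >= 1, n_gen >= 1, n_iterations >= 1, exp_rate >= 0, tol >= 0)
  structure(list(K = as.integer(K), n_gen = n_gen, exp_rate = exp_rate,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), refill = isTRUE(refill),
                 tol = tol, alpha_update = match.arg(alpha_update)),
            class = "hmm_params")
}

#' Per-interval jump probabilities of the copying chains
#'
#' Maps the genetic map to the probability that a copying chain resamples
#' its ancestral haplotype across each interval between adjacent sites:
#' `rho = 1 - exp(-n_gen * exp_rate * d_Mb / 100)`, a Haldane-style
#' conversion of the cM distance accumulated over `n_gen` generations.
#' Chromosome boundaries get `rho = 1` so the chains reset between
#' chromosomes.
#'
#' @param map A `genome_map`.
#' @param n_gen Generations since founding.
#' @param exp_rate Recombination rate in cM/Mb.
#' @return A `transition_schedule`: list with `rho` (length `T - 1`).
#' @export
transition_schedule <- function(map, n_gen = 2, exp_rate = 2) {
  stopifnot(inherits(map, "genome_map"))
  pos <- map$sites$pos
  chrom <- map$sites$chrom
  TT <- length(pos)
  if (TT < 2) stop("need at least 2 sites")
  d_mb <- diff(pos) / 1e6
  rho <- 1 - exp(-n_gen * exp_rate * d_mb / 100)
  rho[chrom[-1] != chrom[-TT]] <- 1
  structure(list(rho = rho, n_gen = n_gen, exp_rate = exp_rate),
            class = "transition_schedule")
}

#' Likelihood of a read stack given an allele dosage probability
#'
#' Product over independent reads: an alternate read has probability
#' `p_alt (1 - eps) + (1 - p_alt) eps`, a reference read the complement.
#' All arguments are vectorized.
#'
#' @param ref_count,alt_count Non-negative read counts.
#' @param p_alt Probability that a sampled allele is the alternate allele.
#' @param base_error Per-read error probability `eps`.
#' @return The likelihood (1 for an empty read stack).
#' @export
emission_likelihood <- function(ref_count, alt_count, p_alt, base_error) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0),
            all(p_alt >= 0 & p_alt <= 1))
  p <- p_alt * (1 - base_error) + (1 - p_alt) * base_error
  p^alt_count * (1 - p)^ref_count
}

#' Diploid forward-backward pass for one sample
#'
#' The hidden state at each site is an ordered pair of ancestral
#' haplotypes, one per chromosome copy; the two copying chains jump
#' independently across each interval with the schedule's probability,
#' landing on haplotype `k` with probability `alpha[k]` (the current
#' haplotype included).  The emission marginalises the two latent allele
#' copies (Bernoulli in the haplotypes' alternate-allele dosages) over the
#' read-stack likelihood.  The recursion is scaled, so arbitrary sequence
#' lengths are underflow-safe, and the returned log-likelihood is exact.
#'
#' @param reads A `T x 2` matrix of (ref, alt) read counts.
#' @param theta `K x T` matrix of ancestral alternate-allele dosages.
#' @param schedule A `transition_schedule` over the same sites.
#' @param alpha Haplotype weights (must sum to 1); uniform by default.
#' @param base_error Per-read error probability.
#' @return List with `posteriors` (a `K x K x T` array of joint-state
#'   posteriors; each site's slice sums to 1) and `loglik`.
#' @export
forward_backward_diploid <- function(reads, theta, schedule, alpha = NULL,
                                     base_error = 0.01) {
  reads <- as.matrix(reads)
  TT <- nrow(reads)
  if (TT == 0) stop("no sites")
  K <- nrow(theta)
  stopifnot(ncol(theta) == TT, ncol(reads) == 2,
            length(schedule$rho) == TT - 1)
  if (is.null(alpha)) alpha <- rep(1 / K, K)
  if (abs(sum(alpha) - 1) > 1e-8) stop("alpha must sum to 1")
  res <- .fb_diploid_cpp(as.numeric(reads[, 1]), as.numeric(reads[, 2]),
                         theta, schedule$rho, alpha, base_error)
  list(posteriors = res$gamma, loglik = res$loglik)
}

#' One EM update of the ancestral haplotypes
#'
#' Re-estimates every haplotype's alternate-allele dosage as the expected
#' number of alternate alleles carried by the chains copying it, divided
#' by the expected number of copying chains, using the joint-state
#' posteriors of the current model.  Sites where a haplotype receives no
#' posterior mass keep their previous value; the result is clipped to
#' `[1e-4, 1 - 1e-4]` to avoid degenerate likelihoods.
#'
#' @param theta Current `K x T` dosage matrix.
#' @param posteriors List (one element per sample) of `K x K x T` joint
#'   posteriors from [forward_backward_diploid()].
#' @param reads List (one element per sample) of `T x 2` (ref, alt) count
#'   matrices.
#' @param base_error Per-read error probability.
#' @return List with the updated `theta` and `alpha` (normalized mean
#'   marginal haplotype usage).
#' @export
em_update <- function(theta, posteriors, reads, base_error) {
  K <- nrow(theta); TT <- ncol(theta)
  stopifnot(length(posteriors) == length(reads), length(reads) >= 1)
  num <- den <- matrix(0, K, TT)
  usage <- numeric(K)
  i1 <- rep(seq_len(K), times = K)   # chain-1 haplotype per joint state
  i2 <- rep(seq_len(K), each = K)    # chain-2 haplotype per joint state
  for (i in seq_along(reads)) {
    rd <- as.matrix(reads[[i]])
    g <- matrix(posteriors[[i]], nrow = K * K)   # KK x T
    L0 <- emission_likelihood(rd[, 1], rd[, 2], 0, base_error)
    L1 <- emission_likelihood(rd[, 1], rd[, 2], 0.5, base_error)
    L2 <- emission_likelihood(rd[, 1], rd[, 2], 1, base_error)
    th1 <- theta[i1, , drop = FALSE]             # KK x T
    th2 <- theta[i2, , drop = FALSE]
    e <- (1 - th1) * (1 - th2) * rep(L0, each = K * K) +
      (th1 + th2 - 2 * th1 * th2) * rep(L1, each = K * K) +
      th1 * th2 * rep(L2, each = K * K)
    pa1 <- (th1 * (1 - th2) * rep(L1, each = K * K) +
              th1 * th2 * rep(L2, each = K * K)) / e
    pa2 <- ((1 - th1) * th2 * rep(L1, each = K * K) +
              th1 * th2 * rep(L2, each = K * K)) / e
    num <- num + rowsum(g * pa1, i1) + rowsum(g * pa2, i2)
    den <- den + rowsum(g, i1) + rowsum(g, i2)
    usage <- usage + rowSums(rowsum(g, i1)) + rowSums(rowsum(g, i2))
  }
  theta_new <- ifelse(den > 1e-12, num / pmax(den, 1e-300), theta)
  theta_new <- pmin(pmax(theta_new, 1e-4), 1 - 1e-4)
  dimnames(theta_new) <- dimnames(theta)
  list(theta = theta_new, alpha = as.vector(usage / sum(usage)))
}

#' Run the full EM imputation engine on a cohort
#'
#' Alternates a diploid haplotype-copying HMM over `K` ancestral
#' haplotypes (E-step over all samples) with re-estimation of the
#' haplotypes' allele dosages (M-step), starting from randomly initialized
#' haplotypes, then produces per-sample genotype posteriors from a final
#' E-pass.  With the default settings (`refill = FALSE`,
#' `alpha_update = "jump"`), each iteration is an exact EM step, so the
#' total log-likelihood is non-decreasing.
#'
#' @param cohort A `sim_cohort` with read counts (or any list exposing
#'   `ref_count`, `alt_count`, `base_error`, `samples`).
#' @param map A `genome_map` aligned to the cohort's sites.
#' @param params An `hmm_params` object.
#' @return An `imputation_result`: list with `dosage` (samples x sites
#'   expected alternate-allele count in \[0, 2\]), `gp` (samples x sites x
#'   3 genotype posterior array), `info` (per-site info score),
#'   `loglik_trace` (one value per E-pass, the final output pass
#'   included), `theta` (the `K x T` reconstructed haplotype dosages),
#'   `alpha`, `usage` (mean per-haplotype usage) and `params`.
#' @export
run_em <- function(cohort, map, params) {
  stopifnot(inherits(params, "hmm_params"))
  if (is.null(cohort$ref_count)) stop("cohort has no read counts")
  N <- nrow(cohort$ref_count); TT <- ncol(cohort$ref_count)
  if (N < 1) stop("empty cohort")
  if (TT < 2) stop("need at least 2 sites")
  stopifnot(n_sites(map) == TT)
  sched <- transition_schedule(map, params$n_gen, params$exp_rate)
  K <- params$K
  eps <- cohort$base_error
  if (is.na(eps)) stop("cohort base_error is not set")

  set.seed(params$seed)
  theta <- matrix(runif(K * TT, 0.1, 0.9), K, TT)
  alpha <- rep(1 / K, K)
  refill_at <- if (params$refill)
    unique(pmax(1, floor(params$n_iterations * c(1 / 4, 1 / 2)))) else integer(0)

  refm <- cohort$ref_count; altm <- cohort$alt_count
  storage.mode(refm) <- "double"; storage.mode(altm) <- "double"
  loglik <- numeric(0)
  for (it in seq_len(params$n_iterations)) {
    pass <- .em_pass_cpp(refm, altm, theta, sched$rho, alpha, eps, FALSE)
    loglik[it] <- sum(pass$loglik)
    theta <- ifelse(pass$den > 1e-12, pass$num / pmax(pass$den, 1e-300),
                    theta)
    theta <- pmin(pmax(theta, 1e-4), 1 - 1e-4)
    if (params$alpha_update == "jump") {
      alpha <- pass$jump / sum(pass$jump)
    } else if (params$alpha_update == "usage") {
      alpha <- pass$usage / sum(pass$usage)
    }
    if (it %in% refill_at) {
      usage <- pass$usage / sum(pass$usage)
      weak <- which(usage < 1 / (4 * K))
      if (length(weak) > 0) {
        best <- which.max(usage)
        for (k in weak)
          theta[k, ] <- pmin(pmax(theta[best, ] + runif(TT, -0.1, 0.1),
                                  1e-4), 1 - 1e-4)
      }
    }
    if (params$tol > 0 && it > 1 &&
        (loglik[it] - loglik[it - 1]) < params$tol * abs(loglik[it]))
      break
  }
  final <- .em_pass_cpp(refm, altm, theta, sched$rho, alpha, eps, TRUE)
  loglik <- c(loglik, sum(final$loglik))

  gp <- array(c(final$gp0, final$gp1, final$gp2), dim = c(N, TT, 3))
  dimnames(final$dosage) <- dimnames(cohort$ref_count)
  structure(list(dosage = final$dosage, gp = gp,
                 info = info_scores(gp),
                 loglik_trace = loglik, theta = theta, alpha = alpha,
                 usage = final$usage / sum(final$usage),
                 sample_ids = cohort$samples$sample_id,
                 params = params),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("imputation_result:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "sites, K =", x$params$K, "\n  final loglik",
      format(tail_value(x$loglik_trace), digits = 10), "after",
      length(x$loglik_trace) - 1, "EM iterations\n")
  invisible(x)
}

tail_value <- function(x) x[length(x)]

#' IMPUTE-style info score at one site
#'
#' `info = 1 - mean posterior dosage variance / (2 f (1 - f))` with `f`
#' the estimated allele frequency (mean dosage / 2).  Values near 1 mean
#' the genotype posteriors are close to point masses; the score is
#' undefined (`NA`) at sites whose estimated frequency is 0 or 1.
#'
#' @param genotype_probs Samples x 3 matrix of genotype posteriors
#'   (P(0), P(1), P(2)) at one site.
#' @return A value in \[0, 1\], or `NA` when undefined.
#' @export
info_score <- function(genotype_probs) {
  gp <- as.matrix(genotype_probs)
  stopifnot(ncol(gp) == 3, nrow(gp) >= 1)
  ds <- gp[, 2] + 2 * gp[, 3]
  v <- gp[, 2] + 4 * gp[, 3] - ds^2
  f <- mean(ds) / 2
  if (f <= 0 || f >= 1) return(undefined_value())
  1 - mean(v) / (2 * f * (1 - f))
}

# vectorized info score across all sites of a gp array (N x T x 3)
info_scores <- function(gp) {
  N <- dim(gp)[1]
  ds <- matrix(gp[, , 2] + 2 * gp[, , 3], nrow = N)
  v <- matrix(gp[, , 2] + 4 * gp[, , 3], nrow = N) - ds^2
  f <- colMeans(ds) / 2
  out <- 1 - colMeans(v) / (2 * f * (1 - f))
  out[f <= 0 | f >= 1] <- undefined_value()
  out
}
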