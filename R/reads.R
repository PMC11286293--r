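#' Simulate low-coverage read counts for a cohort
#'
#' Per (sample, site), the number of reads is Poisson with mean equal to
#' the sample's depth; each read is an alternate-allele read with
#' probability `p (1 - eps) + (1 - p) eps`, where `p = genotype / 2` and
#' `eps` is the per-read base error.  Per-sample depths are drawn from a
#' Gamma distribution with the requested mean (coefficient of variation
#' `depth_cv`) to emulate the heterogeneous depths of real multiplexed
#' sequencing runs; truth samples instead get a fixed high depth.
#'
#' @param cohort A `sim_cohort` with truth genotypes.
#' @param mean_depth Target mean coverage of the low-coverage samples.
#' @param base_error Per-read error probability, in \[0, 0.5).
#' @param seed Optional integer seed.
#' @param depth_cv Coefficient of variation of the per-sample depth
#'   distribution; 0 gives every low-coverage sample exactly `mean_depth`.
#' @param truth_depth Depth of the high-coverage truth samples.
#' @return The cohort with `ref_count`/`alt_count` matrices filled, the
#'   per-sample `target_depth` recorded in `samples`, and `base_error` set.
#' @export
simulate_reads <- function(cohort, mean_depth = 1.4, base_error = 0.01,
                           seed = NULL, depth_cv = 0.5, truth_depth = 40) {
  stopifnot(inherits(cohort, "sim_cohort"), mean_depth >= 0,
            base_error >= 0, base_error < 0.5)
  if (!is.null(seed)) set.seed(seed)
  N <- n_samples(cohort); TT <- ncol(cohort$truth_geno)
  depth <- if (mean_depth == 0 || depth_cv == 0) {
    rep(mean_depth, N)
  } else {
    shape <- 1 / depth_cv^2
    rgamma(N, shape = shape, rate = shape / mean_depth)
  }
  depth[cohort$samples$is_truth] <- truth_depth
  n_reads <- matrix(rpois(N * TT, rep(depth, TT)), nrow = N)
  p_alt <- cohort$truth_geno / 2
  p_read <- p_alt * (1 - base_error) + (1 - p_alt) * base_error
  alt <- matrix(rbinom(N * TT, n_reads, p_read), nrow = N)
  cohort$alt_count <- alt
  cohort$ref_count <- n_reads - alt
  dimnames(cohort$alt_count) <- dimnames(cohort$ref_count) <-
    dimnames(cohort$truth_geno)
  cohort$samples$target_depth <- depth
  cohort$base_error <- base_error
  cohort
}

#' Realized mean sequencing depth per sample
#'
#' @param cohort A `sim_cohort` with read counts.
#' @return Named numeric vector: total reads divided by site count.
#' @export
realized_depth <- function(cohort) {
  stopifnot(!is.null(cohort$ref_count))
  rowMeans(cohort$ref_count + cohort$alt_count)
}

#' Restrict a cohort to a subset of sites
#'
#' @param cohort A `sim_cohort`.
#' @param idx Site indices to retain.
#' @return The cohort restricted to those sites (column subset of all
#'   site-indexed matrices).
#' @export
subset_sites <- function(cohort, idx) {
  idx <- sort(unique(as.integer(idx)))
  stopifnot(length(idx) >= 1, min(idx) >= 1,
            max(idx) <= ncol(cohort$truth_geno))
  cohort$truth_geno <- cohort$truth_geno[, idx, drop = FALSE]
  if (!is.null(cohort$ref_count)) {
    cohort$ref_count <- cohort$ref_count[, idx, drop = FALSE]
    cohort$alt_count <- cohort$alt_count[, idx, drop = FALSE]
  }
  cohort
}

# row subset of a cohort, keeping all per-sample tables aligned
subset_samples <- function(cohort, idx) {
  idx <- as.integer(idx)
  cohort$samples <- cohort$samples[idx, , drop = FALSE]
  rownames(cohort$samples) <- NULL
  cohort$truth_geno <- cohort$truth_geno[idx, , drop = FALSE]
  if (!is.null(cohort$ref_count)) {
    cohort$ref_count <- cohort$ref_count[idx, , drop = FALSE]
    cohort$alt_count <- cohort$alt_count[idx, , drop = FALSE]
  }
  if (!is.null(cohort$origin)) cohort$origin <- cohort$origin[idx]
  cohort
}
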