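#' Plan for iterative SNP-set refinement
#'
#' @param thresholds Per-iteration minimum squared correlation; the default
#'   is the five-round schedule 0.5, 0.5, 0.75, 0.9, 0.9.
#' @param truth_target_depth Coverage to which truth samples are thinned
#'   before each joint imputation, so they resemble the cohort they are
#'   imputed with (default 0.5x).
#' @return A `refinement_plan`.
#' @export
refinement_plan <- function(thresholds = c(0.5, 0.5, 0.75, 0.9, 0.9),
                            truth_target_depth = 0.5) {
  stopifnot(length(thresholds) >= 1, all(thresholds >= 0 & thresholds <= 1),
            truth_target_depth > 0)
  structure(list(thresholds = thresholds,
                 truth_target_depth = truth_target_depth),
            class = "refinement_plan")
}

#' Initial SNP set: sites polymorphic among the truth samples
#'
#' Retains sites with a minor allele count of at least 1 within the
#' ground-truth samples, i.e. sites at which the truth samples are not all
#' homozygous for the same allele.  (In simulation every site is biallelic
#' and no excluded contigs exist, so polymorphism is the only active
#' filter.)
#'
#' @param cohort A `sim_cohort` with at least one truth sample.
#' @return Sorted integer site indices.
#' @export
initial_snp_set <- function(cohort) {
  ti <- truth_idx(cohort)
  if (length(ti) < 1) stop("cohort has no truth samples")
  g <- cohort$truth_geno[ti, , drop = FALSE]
  ac <- colSums(g)
  mac <- pmin(ac, 2 * length(ti) - ac)
  keep <- which(mac >= 1)
  if (length(keep) == 0) stop("no polymorphic sites among truth samples")
  keep
}

#' Per-SNP squared correlation between imputed dosage and truth
#'
#' @param dosage Truth-samples x sites matrix of imputed dosages.
#' @param truth Matching matrix of true genotypes (0/1/2).
#' @return Per-site r^2; `NA` where either vector has zero variance.
#' @export
per_snp_r2 <- function(dosage, truth) {
  dosage <- as.matrix(dosage); truth <- as.matrix(truth)
  stopifnot(all(dim(dosage) == dim(truth)), nrow(dosage) >= 2)
  vapply(seq_len(ncol(dosage)), function(t)
    pearson_r2(dosage[, t], truth[, t]), numeric(1))
}

#' Iteratively refine the imputable SNP set
#'
#' Starting from the sites polymorphic in the truth samples, each round
#' thins the truth samples' reads to `plan$truth_target_depth`, imputes
#' the whole cohort jointly on the current site set, scores every site by
#' the squared correlation of the truth samples' imputed dosages with
#' their true genotypes, and drops sites below the round's threshold
#' (sites with undefined r^2 cannot be validated and are dropped too).
#'
#' @param cohort A `sim_cohort` with read counts and truth samples.
#' @param map A `genome_map` over the cohort's sites.
#' @param params An `hmm_params`.
#' @param plan A `refinement_plan`.
#' @param impute_fun Imputation engine, `function(cohort, map, params)`
#'   returning an object with a `dosage` matrix; [run_em()] by default
#'   (injectable for testing).
#' @return A `refinement_trace`: list with `trace` (data frame per
#'   iteration: threshold, sites in/out, mean per-truth-sample r^2) and
#'   `sites` (final retained site indices, a subset of the initial set).
#' @export
refine_snp_set <- function(cohort, map, params, plan = refinement_plan(),
                           impute_fun = run_em) {
  stopifnot(inherits(plan, "refinement_plan"))
  ti <- truth_idx(cohort)
  if (length(ti) < 2) stop("need at least 2 truth samples")
  sites <- initial_snp_set(cohort)
  trace <- data.frame(iteration = integer(0), threshold = numeric(0),
                      n_before = integer(0), n_after = integer(0),
                      mean_sample_r2 = numeric(0))
  for (i in seq_along(plan$thresholds)) {
    sub <- subset_sites(cohort, sites)
    sub <- downsample_depth(sub, d_target = NULL,
                            truth_target = plan$truth_target_depth,
                            seed = params$seed + 7919L * i)
    fit <- impute_fun(sub, subset_map(map, sites), params)
    truth_dosage <- fit$dosage[ti, , drop = FALSE]
    truth_geno <- sub$truth_geno[ti, , drop = FALSE]
    r2 <- per_snp_r2(truth_dosage, truth_geno)
    keep <- !is.na(r2) & r2 >= plan$thresholds[i]
    sample_r2 <- per_sample_concordance(truth_dosage, truth_geno)$mean_r2
    trace <- rbind(trace, data.frame(
      iteration = i, threshold = plan$thresholds[i],
      n_before = length(sites), n_after = sum(keep),
      mean_sample_r2 = sample_r2))
    if (!any(keep))
      stop("refinement dropped all sites at iteration ", i)
    sites <- sites[keep]
  }
  structure(list(trace = trace, sites = sites), class = "refinement_trace")
}

#' @export
print.refinement_trace <- function(x, ...) {
  cat("refinement_trace:\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}
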