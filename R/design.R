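#' Thin read counts to a target mean depth
#'
#' Per sample, the downsampling factor is `f = d_target / d_original`
#' capped at 1 (samples already below the target are left untouched), and
#' every read is independently retained with probability `f` (binomial
#' thinning, the in-simulation analogue of read subsampling on
#' alignments).  Truth samples are thinned to `truth_target`, which
#' defaults to the cohort's target; when the cohort keeps its original
#' depth (`d_target = NULL`), truth samples are thinned to 0.5x so that
#' their evaluation is not inflated by their high coverage.
#'
#' @param cohort A `sim_cohort` with read counts.
#' @param d_target Target mean depth for the low-coverage samples, or
#'   `NULL` to keep their original depth.
#' @param seed Optional integer seed.
#' @param truth_target Target mean depth for the truth samples.
#' @return The cohort with thinned read counts.
#' @export
downsample_depth <- function(cohort, d_target, seed = NULL,
                             truth_target = if (is.null(d_target)) 0.5
                                            else d_target) {
  stopifnot(!is.null(cohort$ref_count))
  if (!is.null(d_target) && d_target <= 0) stop("d_target must be positive")
  if (truth_target <= 0) stop("truth_target must be positive")
  if (!is.null(seed)) set.seed(seed)
  d_orig <- realized_depth(cohort)
  is_truth <- cohort$samples$is_truth
  target <- if (is.null(d_target)) d_orig else rep(d_target, length(d_orig))
  target[is_truth] <- truth_target
  f <- pmin(1, target / pmax(d_orig, .Machine$double.eps))
  for (i in which(f < 1)) {
    cohort$ref_count[i, ] <- rbinom(ncol(cohort$ref_count),
                                    cohort$ref_count[i, ], f[i])
    cohort$alt_count[i, ] <- rbinom(ncol(cohort$alt_count),
                                    cohort$alt_count[i, ], f[i])
  }
  cohort
}

#' Downsample the number of samples, always retaining truth samples
#'
#' @param cohort A `sim_cohort`.
#' @param n_target Desired cohort size (truth samples included); must be
#'   between the number of truth samples and the cohort size.
#' @param seed Optional integer seed.
#' @return The downsampled cohort: all truth samples plus a uniform random
#'   subset of the rest, ignoring cross membership; original sample order
#'   is preserved.
#' @export
downsample_samples <- function(cohort, n_target, seed = NULL) {
  ti <- truth_idx(cohort)
  N <- n_samples(cohort)
  if (n_target < length(ti))
    stop("n_target smaller than the number of truth samples")
  if (n_target > N) stop("n_target larger than the cohort")
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(seq_len(N), ti)
  keep <- sort(c(ti, sample(pool, n_target - length(ti))))
  subset_samples(cohort, keep)
}

#' Iteratively remove founder lines (and their crosses) from a design
#'
#' At each step, every cross involving the removed line is dropped, along
#' with all samples belonging to it (truth samples included), and the
#' remaining numbers of founder lines and crosses are recorded.  Applied
#' to the 10-cross reference design with the default removal order, the
#' (lines, crosses) sequence after each step is (7, 9), (6, 7), (5, 6),
#' (4, 4), (3, 3), (2, 1), the last step leaving the single 72-2 x 55-2
#' cross.
#'
#' @param design A `cross_design`.
#' @param removal_order Founder lines to remove, in order; the default is
#'   the reference order 22-1, 68-1, 79-2, 15-1, 62-2, 139-4.
#' @param cohort Optional `sim_cohort` simulated from `design`; when
#'   given, the matching sample subsets are returned per step.
#' @return List with `steps` (data frame: step 0 is the full design, then
#'   one row per removal with `removed_line`, `n_lines`, `n_crosses`,
#'   `n_samples`), `designs` and (when a cohort was given) `cohorts`.
#' @export
downsample_crosses <- function(design,
                               removal_order = c("22-1", "68-1", "79-2",
                                                 "15-1", "62-2", "139-4"),
                               cohort = NULL) {
  stopifnot(inherits(design, "cross_design"))
  all_lines <- design_summary(design)$lines
  unknown <- setdiff(removal_order, all_lines)
  if (length(unknown) > 0)
    stop("unknown line(s) in removal order: ",
         paste(unknown, collapse = ", "))
  cur <- design
  cur_cohort <- cohort
  count_samples <- function(d, co) {
    if (!is.null(co)) nrow(co$samples) else sum(d$crosses$n_f2)
  }
  steps <- data.frame(step = 0L, removed_line = NA_character_,
                      n_lines = design_summary(cur)$n_lines,
                      n_crosses = design_summary(cur)$n_crosses,
                      n_samples = count_samples(cur, cur_cohort))
  designs <- list(cur)
  cohorts <- if (!is.null(cohort)) list(cur_cohort)
  for (s in seq_along(removal_order)) {
    line <- removal_order[s]
    keep <- cur$crosses$sire != line & cur$crosses$dam != line
    if (!any(keep)) stop("removal of line ", line, " leaves no crosses")
    dropped_ids <- cur$crosses$id[!keep]
    cur$crosses <- cur$crosses[keep, , drop = FALSE]
    rownames(cur$crosses) <- NULL
    if (!is.null(cur_cohort)) {
      keep_s <- !(cur_cohort$samples$cross %in% dropped_ids)
      cur_cohort <- subset_samples(cur_cohort, which(keep_s))
      cohorts[[s + 1L]] <- cur_cohort
    }
    ds <- design_summary(cur)
    steps <- rbind(steps, data.frame(
      step = s, removed_line = line, n_lines = ds$n_lines,
      n_crosses = ds$n_crosses,
      n_samples = count_samples(cur, cur_cohort)))
    designs[[s + 1L]] <- cur
  }
  out <- list(steps = steps, designs = designs)
  if (!is.null(cohort)) out$cohorts <- cohorts
  out
}

#' Number of ancestral haplotypes from the number of founder lines
#'
#' The rule used throughout: `K` is twice the number of founder lines
#' contributing to the imputed population (16 for the eight-founder
#' reference design, 4 for a single cross of two lines).
#'
#' @param n_founder_lines Number of founder lines (>= 1).
#' @return The `K` to use.
#' @export
choose_k <- function(n_founder_lines) {
  stopifnot(n_founder_lines >= 1)
  2L * as.integer(n_founder_lines)
}

#' Sequencing and library preparation cost parameters
#'
#' Defaults are the reference constants: a 734,040,372 bp haploid genome,
#' a mean flow-cell output of 273,542,732,637 bp after deduplication, and
#' a flow-cell to per-library cost ratio of 683.89 (costs are expressed in
#' per-library units, `cp = 1`).
#'
#' @param g Haploid genome size in bp.
#' @param flowcell_output Mean sequenced bp per flow cell.
#' @param cf Cost per flow cell.
#' @param cp Cost per sample library.
#' @return A `cost_params` object.
#' @export
cost_params <- function(g = 734040372, flowcell_output = 273542732637,
                        cf = 683.89, cp = 1) {
  stopifnot(g > 0, flowcell_output > 0, cf > 0, cp > 0)
  structure(list(g = g, flowcell_output = flowcell_output, cf = cf,
                 cp = cp), class = "cost_params")
}

#' Sequencing study cost
#'
#' `cost = (n d g / f) cf + n cp`: the flow-cell fraction needed to
#' sequence `n` samples at mean depth `d` over a genome of size `g`
#' (sequencing treated as continuously divisible), plus one library per
#' sample.
#'
#' @param n Number of samples.
#' @param d Mean sequencing depth.
#' @param params A `cost_params`.
#' @return Cost in the parameter's units (`cp`-multiples when `cp = 1`).
#' @export
cost <- function(n, d, params = cost_params()) {
  stopifnot(all(n >= 0), all(d >= 0))
  (n * d * params$g / params$flowcell_output) * params$cf + n * params$cp
}

#' Cost of a design relative to a reference design
#'
#' @param n,d Samples and mean depth of the candidate design.
#' @param n_ref,d_ref Samples and mean depth of the reference design.
#' @param params A `cost_params`.
#' @return `cost(n, d) / cost(n_ref, d_ref)`.
#' @export
relative_cost <- function(n, d, n_ref, d_ref, params = cost_params()) {
  ref <- cost(n_ref, d_ref, params)
  if (any(ref <= 0)) stop("reference cost must be positive")
  cost(n, d, params) / ref
}

#' Cost-versus-accuracy sweep over sample number and sequencing depth
#'
#' For every combination of cohort size, target depth and replicate, the
#' base cohort is downsampled in samples then in depth, imputed with
#' [run_em()], and scored by the mean per-truth-sample squared
#' correlation; the cost of the scenario is reported relative to the base
#' cohort (its full size at its realized low-coverage mean depth).  A
#' depth of `NA` in the grid keeps the original per-sample depths (truth
#' samples are then thinned to 0.5x) and is costed at the reference
#' depth.
#'
#' @param cohort The base `sim_cohort` with read counts and truth samples.
#' @param map A `genome_map` over the cohort's sites.
#' @param n_grid Cohort sizes to evaluate (truth samples included).
#' @param depth_grid Target mean depths to evaluate (may contain `NA`).
#' @param params An `hmm_params` used for every run (its seed is combined
#'   with `seed` and the replicate index).
#' @param cparams A `cost_params`.
#' @param replicates Number of random replicates per grid point.
#' @param seed Integer seed for the downsampling randomness.
#' @return A `sweep_result` data frame: `n`, `depth`, `replicate`,
#'   `seed`, `mean_r2`, `relative_cost`, in deterministic row order.
#' @export
sweep_design <- function(cohort, map, n_grid, depth_grid, params,
                         cparams = cost_params(), replicates = 3,
                         seed = 1) {
  stopifnot(length(n_grid) >= 1, length(depth_grid) >= 1, replicates >= 1)
  n_ref <- n_samples(cohort)
  d_ref <- mean(realized_depth(cohort)[!cohort$samples$is_truth])
  rows <- list()
  combo <- 0L
  for (n in n_grid) for (d in depth_grid) {
    combo <- combo + 1L
    for (r in seq_len(replicates)) {
      run_seed <- as.integer(seed + 1009L * combo + 101L * r)
      sub <- downsample_samples(cohort, n, seed = run_seed)
      sub <- downsample_depth(sub, if (is.na(d)) NULL else d,
                              seed = run_seed + 1L)
      p <- params
      p$seed <- run_seed
      fit <- run_em(sub, map, p)
      ti <- truth_idx(sub)
      conc <- per_sample_concordance(fit$dosage[ti, , drop = FALSE],
                                     sub$truth_geno[ti, , drop = FALSE])
      rc <- relative_cost(n, if (is.na(d)) d_ref else d, n_ref, d_ref,
                          cparams)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, depth = d, replicate = r, seed = run_seed,
        mean_r2 = conc$mean_r2, relative_cost = rc)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}
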