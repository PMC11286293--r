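#' Default run configuration
#'
#' Nested list of parameters for every pipeline stage.  Model settings
#' default to the reference analysis values (nGen = 2, expRate = 2
#' cM/Mb, 100 EM iterations, truth samples thinned to 0.5x, the
#' five-round refinement schedule 0.5/0.5/0.75/0.9/0.9, K chosen as twice
#' the number of founder lines, the K-scan grid 2/4/8/16/24, and the
#' reference cost constants), while the simulated problem size defaults
#' to a desk scale: one 5 Mb chromosome with 1000 SNPs and the 10-cross
#' design scaled to about 110 F2 samples.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "crossimpute_run",
    genome = list(n_chrom = 1L, chrom_len = 5e6, n_sites = 1000L,
                  exp_rate = 2),
    founders = list(residual_het = 0.01),
    cross = list(design = "medaka", scale = 0.05, n_f1 = 4L),
    reads = list(mean_depth = 1.4, base_error = 0.01, depth_cv = 0.5,
                 truth_depth = 40),
    impute = list(K = NULL, n_gen = 2, exp_rate = 2, n_iterations = 100L,
                  refill = FALSE, tol = 1e-5, alpha_update = "jump"),
    kscan = list(grid = c(2L, 4L, 8L, 16L, 24L), enabled = TRUE),
    refine = list(thresholds = c(0.5, 0.5, 0.75, 0.9, 0.9),
                  truth_target_depth = 0.5),
    sweep = list(enabled = FALSE, n_grid = NULL, depth_grid = NULL,
                 replicates = 3L),
    cost = list(g = 734040372, flowcell_output = 273542732637,
                cf = 683.89, cp = 1)
  )
}

# recursively overlay user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section ", paste(path, collapse = "$"),
                           " must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste(c(paste(path, collapse = "$"), unknown), collapse = "$"))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a run configuration
#'
#' Reads a YAML file, overlays it onto [default_config()] and rejects
#' unknown keys before any stage runs.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides Optional named list applied on top of the file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  stopifnot(cfg$seed == as.integer(cfg$seed))
  cfg
}

#' Scan the number of ancestral haplotypes
#'
#' Runs the imputation once per candidate `K` on the cohort (truth
#' samples thinned beforehand by the caller) and reports the mean
#' per-truth-sample squared correlation; the best `K` maximizes it, with
#' ties broken toward the smaller `K`.
#'
#' @param cohort A `sim_cohort` with read counts (truth samples already
#'   thinned to their evaluation depth).
#' @param map A `genome_map`.
#' @param params An `hmm_params` whose `K` is ignored.
#' @param grid Candidate `K` values.
#' @return List with `table` (data frame: K, mean_r2) and `best_k`.
#' @export
kscan <- function(cohort, map, params, grid = c(2L, 4L, 8L, 16L, 24L)) {
  ti <- truth_idx(cohort)
  if (length(ti) < 2) stop("need at least 2 truth samples")
  r2 <- vapply(grid, function(k) {
    p <- params
    p$K <- as.integer(k)
    fit <- run_em(cohort, map, p)
    per_sample_concordance(fit$dosage[ti, , drop = FALSE],
                           cohort$truth_geno[ti, , drop = FALSE])$mean_r2
  }, numeric(1))
  best <- grid[which.max(r2)]  # which.max takes the first (smallest) tie
  list(table = data.frame(K = grid, mean_r2 = r2), best_k = best)
}

#' Run the full pipeline: simulate, scan K, refine, re-scan, evaluate
#'
#' Executes the end-to-end analysis on synthetic data: cohort simulation,
#' a K-scan on the unfiltered polymorphic site set, iterative SNP-set
#' refinement at the chosen K, a K re-scan on the refined set, a final
#' imputation with per-sample and MAF-binned concordance reports, and
#' optionally a cost-versus-accuracy sweep.  All stage outputs (VCFs,
#' TSV tables) plus a manifest recording the configuration, seeds and
#' output files are written under the output directory; given the same
#' configuration and seed the run is fully reproducible.
#'
#' @param config A configuration list from [read_run_config()].
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-stage results (`map`, `cohort`
#'   paths, `kscan_initial`, `refinement`, `kscan_refined`, `concordance`,
#'   `sweep`, `manifest`).
#' @export
full_run <- function(config = read_run_config(), out_dir = config$out_dir,
                     quiet = FALSE) {
  say <- function(...) if (!quiet) message("[crossimpute] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  paths <- list()

  say("simulating cohort")
  map <- make_genome_map(config$genome$n_chrom, config$genome$chrom_len,
                         config$genome$n_sites, config$genome$exp_rate,
                         seed = seed)
  design <- if (identical(config$cross$design, "medaka")) {
    medaka_cross_design(scale = config$cross$scale)
  } else {
    cross_design(do.call(rbind, lapply(config$cross$design, function(x)
      data.frame(sire = x[[1]], dam = x[[2]],
                 n_f2 = as.integer(x[[3]])))))
  }
  lines <- design_summary(design)$lines
  panel <- simulate_founders(map, n_lines = length(lines),
                             residual_het = config$founders$residual_het,
                             seed = seed + 1L, line_ids = lines)
  cohort <- simulate_cross(panel, design, map, seed = seed + 2L,
                           n_f1 = config$cross$n_f1)
  cohort <- simulate_reads(cohort, config$reads$mean_depth,
                           config$reads$base_error, seed = seed + 3L,
                           depth_cv = config$reads$depth_cv,
                           truth_depth = config$reads$truth_depth)
  paths$truth_vcf <- file.path(out_dir, "truth.vcf")
  write_vcf(paths$truth_vcf, map, cohort$samples$sample_id,
            geno = cohort$truth_geno)
  paths$reads_vcf <- file.path(out_dir, "reads.vcf")
  write_vcf(paths$reads_vcf, map, cohort$samples$sample_id,
            ref_count = cohort$ref_count, alt_count = cohort$alt_count)
  paths$metadata <- file.path(out_dir, "samples.tsv")
  write_sample_metadata(paths$metadata, cohort)

  base_params <- hmm_params(
    K = if (is.null(config$impute$K)) choose_k(length(lines))
        else config$impute$K,
    n_gen = config$impute$n_gen, exp_rate = config$impute$exp_rate,
    n_iterations = config$impute$n_iterations, seed = seed + 4L,
    refill = config$impute$refill, tol = config$impute$tol,
    alpha_update = config$impute$alpha_update)
  plan <- refinement_plan(config$refine$thresholds,
                          config$refine$truth_target_depth)

  sites0 <- initial_snp_set(cohort)
  scan_cohort <- downsample_depth(subset_sites(cohort, sites0),
                                  d_target = NULL,
                                  truth_target = plan$truth_target_depth,
                                  seed = seed + 5L)
  scan_map <- subset_map(map, sites0)

  results <- list(map = map, paths = paths)
  k_use <- base_params$K
  if (isTRUE(config$kscan$enabled)) {
    say("K-scan on the unfiltered site set")
    ks1 <- kscan(scan_cohort, scan_map, base_params, config$kscan$grid)
    paths$kscan_initial <- file.path(out_dir, "kscan_initial.tsv")
    write.table(ks1$table, paths$kscan_initial, sep = "\t", quote = FALSE,
                row.names = FALSE)
    k_use <- ks1$best_k
    results$kscan_initial <- ks1
  }

  say("refining the SNP set at K = ", k_use)
  p_ref <- base_params
  p_ref$K <- as.integer(k_use)
  refn <- refine_snp_set(cohort, map, p_ref, plan)
  paths$refine_trace <- file.path(out_dir, "refinement_trace.tsv")
  write.table(refn$trace, paths$refine_trace, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$final_sites <- file.path(out_dir, "final_sites.tsv")
  write.table(map$sites[refn$sites, c("chrom", "pos")], paths$final_sites,
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$refinement <- refn

  fin_cohort <- downsample_depth(subset_sites(cohort, refn$sites),
                                 d_target = NULL,
                                 truth_target = plan$truth_target_depth,
                                 seed = seed + 6L)
  fin_map <- subset_map(map, refn$sites)
  if (isTRUE(config$kscan$enabled)) {
    say("K re-scan on the refined site set")
    ks2 <- kscan(fin_cohort, fin_map, base_params, config$kscan$grid)
    paths$kscan_refined <- file.path(out_dir, "kscan_refined.tsv")
    write.table(ks2$table, paths$kscan_refined, sep = "\t", quote = FALSE,
                row.names = FALSE)
    k_use <- ks2$best_k
    results$kscan_refined <- ks2
  }

  say("final imputation at K = ", k_use)
  p_fin <- base_params
  p_fin$K <- as.integer(k_use)
  fit <- run_em(fin_cohort, fin_map, p_fin)
  ti <- truth_idx(fin_cohort)
  conc <- per_sample_concordance(fit$dosage[ti, , drop = FALSE],
                                 fin_cohort$truth_geno[ti, , drop = FALSE])
  maf <- observed_maf(fin_cohort$truth_geno[ti, , drop = FALSE])
  bins <- maf_binned_concordance(fit$dosage[ti, , drop = FALSE],
                                 fin_cohort$truth_geno[ti, , drop = FALSE],
                                 maf)
  paths$imputed_vcf <- file.path(out_dir, "imputed.vcf")
  write_vcf(paths$imputed_vcf, fin_map, fin_cohort$samples$sample_id,
            geno = apply(fit$gp, c(1, 2), which.max) - 1L,
            dosage = fit$dosage, gp = fit$gp, info_score = fit$info)
  paths$per_sample <- file.path(out_dir, "concordance_per_sample.tsv")
  write.table(data.frame(sample_id = fin_cohort$samples$sample_id[ti],
                         r2 = conc$per_sample_r2),
              paths$per_sample, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$maf_bins <- file.path(out_dir, "concordance_maf_bins.tsv")
  write.table(bins, paths$maf_bins, sep = "\t", quote = FALSE,
              row.names = FALSE)
  results$concordance <- list(per_sample = conc, maf_bins = bins,
                              final_k = k_use)

  if (isTRUE(config$sweep$enabled)) {
    say("cost-versus-accuracy sweep")
    sw <- sweep_design(fin_cohort, fin_map,
                       n_grid = config$sweep$n_grid,
                       depth_grid = config$sweep$depth_grid,
                       params = p_fin,
                       cparams = cost_params(config$cost$g,
                                             config$cost$flowcell_output,
                                             config$cost$cf,
                                             config$cost$cp),
                       replicates = config$sweep$replicates,
                       seed = seed + 7L)
    paths$sweep <- file.path(out_dir, "sweep.tsv")
    write.table(sw, paths$sweep, sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$sweep <- sw
  }

  manifest <- list(
    package_version = as.character(packageVersion("crossimpute")),
    config = config, seed = seed,
    stage_seeds = list(map = seed, founders = seed + 1L,
                       cross = seed + 2L, reads = seed + 3L,
                       impute = seed + 4L, scan_thin = seed + 5L,
                       final_thin = seed + 6L, sweep = seed + 7L),
    final_k = k_use,
    mean_r2 = conc$mean_r2,
    n_sites_initial = length(sites0),
    n_sites_final = length(refn$sites),
    outputs = lapply(paths, basename))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  results$paths <- paths
  results$manifest <- manifest
  say("done: ", out_dir)
  invisible(results)
}
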