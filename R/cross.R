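#' Define a set of F2 crosses between founder lines
#'
#' A design is an ordered table of crosses (sire line, dam line, number of
#' F2 individuals) plus a plan for which individuals are sequenced at high
#' coverage and serve as ground truth.  A reciprocal pair of entries
#' (A x B and B x A) counts as a single cross.
#'
#' @param crosses Data frame with columns `sire`, `dam`, `n_f2`.
#' @param f1_truth_per_cross Number of F1 truth samples per (unordered)
#'   cross; default one, attached to the first entry of the cross.
#' @param extra_f2_truth Number of F2 individuals additionally flagged as
#'   truth samples.
#' @param extra_f2_cross Index of the design entry contributing those F2
#'   truth samples.
#' @return A `cross_design`.
#' @export
cross_design <- function(crosses, f1_truth_per_cross = 1,
                         extra_f2_truth = 2, extra_f2_cross = 1) {
  stopifnot(is.data.frame(crosses),
            all(c("sire", "dam", "n_f2") %in% names(crosses)),
            all(crosses$n_f2 >= 0))
  crosses$sire <- as.character(crosses$sire)
  crosses$dam <- as.character(crosses$dam)
  crosses$id <- paste0(crosses$sire, "x", crosses$dam)
  if (anyDuplicated(crosses$id)) stop("duplicated cross entries")
  if (extra_f2_truth > 0 &&
      (extra_f2_cross < 1 || extra_f2_cross > nrow(crosses)))
    stop("extra_f2_cross out of range")
  if (extra_f2_truth > crosses$n_f2[extra_f2_cross])
    stop("more F2 truth samples than F2 samples in the chosen cross")
  structure(list(crosses = crosses,
                 truth_plan = list(f1_per_cross = f1_truth_per_cross,
                                   extra_f2 = extra_f2_truth,
                                   extra_f2_cross = extra_f2_cross)),
            class = "cross_design")
}

# unordered line pair per entry, used to collapse reciprocal crosses
cross_pair_key <- function(design) {
  apply(cbind(design$crosses$sire, design$crosses$dam), 1,
        function(p) paste(sort(p), collapse = "|"))
}

#' Lines and crosses used by a design
#'
#' @param design A `cross_design`.
#' @return List with `n_lines`, `n_crosses` (reciprocal entries counted
#'   once), `lines`.
#' @export
design_summary <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  lines <- unique(c(design$crosses$sire, design$crosses$dam))
  list(n_lines = length(lines),
       n_crosses = length(unique(cross_pair_key(design))),
       lines = lines)
}

#' The 10-cross medaka MIKK-panel design
#'
#' The eight-founder, ten-cross F2 design used throughout the package as
#' the reference study design (the reciprocal 72-2 x 139-4 pair is a single
#' cross performed in both directions).  Per-cross F2 sample counts sum to
#' 2209, of which two are sequenced at high coverage, leaving 2207
#' low-coverage samples; together with one high-coverage F1 per cross this
#' gives 12 truth samples.
#'
#' @param scale Optional factor applied to the per-cross F2 counts
#'   (rounded, kept >= 2); useful for desk-scale runs.
#' @return A `cross_design`.
#' @export
medaka_cross_design <- function(scale = 1) {
  tab <- data.frame(
    sire = c("72-2", "72-2", "72-2", "139-4", "72-2", "72-2",
             "72-2", "68-1", "15-1", "55-2", "72-2"),
    dam  = c("79-2", "15-1", "139-4", "72-2", "55-2", "62-2",
             "68-1", "79-2", "62-2", "139-4", "22-1"),
    n_f2 = c(153, 141, 153, 149, 481, 142, 164, 147, 158, 373, 148),
    stringsAsFactors = FALSE)
  if (scale != 1) tab$n_f2 <- pmax(2L, as.integer(round(tab$n_f2 * scale)))
  cross_design(tab, f1_truth_per_cross = 1, extra_f2_truth = 2,
               extra_f2_cross = 1)
}

# crossover mask for one gamete: returns, per site, which parental
# haplotype (1 or 2) is copied.  Crossovers are Poisson along each
# chromosome with mean exp_rate * length_Mb / 100.
gamete_source <- function(map) {
  src <- integer(n_sites(map))
  for (i in seq_len(nrow(map$chromosomes))) {
    on_chr <- which(map$sites$chrom == map$chromosomes$name[i])
    len <- map$chromosomes$length[i]
    n_co <- rpois(1, map$exp_rate * (len / 1e6) / 100)
    co <- sort(runif(n_co, 0, len))
    start <- sample(1:2, 1)
    seg <- findInterval(map$sites$pos[on_chr], co)
    src[on_chr] <- 1L + (seg + start) %% 2L
  }
  src
}

#' Simulate one meiosis
#'
#' Produces a gamete as a recombinant mosaic of the two parental
#' haplotypes, with a Poisson number of crossovers per chromosome
#' (mean `exp_rate x length_Mb / 100`) placed uniformly.
#'
#' @param parent_hap_a,parent_hap_b Parental haplotypes: 0/1 vectors
#'   aligned to the map sites.
#' @param map A `genome_map` (provides positions and `exp_rate`).
#' @param seed Optional integer seed.
#' @return A 0/1 haplotype vector of the same length.
#' @export
meiosis <- function(parent_hap_a, parent_hap_b, map, seed = NULL) {
  stopifnot(length(parent_hap_a) == n_sites(map),
            length(parent_hap_b) == n_sites(map))
  if (!is.null(seed)) set.seed(seed)
  src <- gamete_source(map)
  ifelse(src == 1L, parent_hap_a, parent_hap_b)
}

#' Simulate an F2 cohort from a founder panel and a cross design
#'
#' For every design entry, F1 individuals are produced from one gamete of
#' the sire line and one of the dam line; F2 individuals are produced from
#' two gametes of two distinct F1 parents.  Two meioses therefore separate
#' every F2 haplotype from the founder haplotypes.  Individuals flagged by
#' the design's truth plan (by default one F1 per cross plus two F2 in the
#' designated cross) are marked as ground-truth samples.
#'
#' @param panel A `founder_panel`.
#' @param design A `cross_design`; every line it names must exist in the
#'   panel.
#' @param map A `genome_map`.
#' @param seed Optional integer seed.
#' @param n_f1 Number of F1 individuals generated per entry to serve as F2
#'   parents (at least 2).
#' @param keep_origin Track the founder haplotype of origin of every F2
#'   gamete allele (stored as integer matrices in `origin`); off by
#'   default.
#' @return A `sim_cohort` with truth genotypes only (see
#'   [simulate_reads()] for read counts): list with `samples` (data frame:
#'   sample_id, cross, generation, is_truth), `truth_geno` (samples x
#'   sites matrix of 0/1/2), `base_error` (NA until reads are simulated).
#' @export
simulate_cross <- function(panel, design, map, seed = NULL, n_f1 = 4,
                           keep_origin = FALSE) {
  stopifnot(inherits(panel, "founder_panel"),
            inherits(design, "cross_design"),
            inherits(map, "genome_map"),
            ncol(panel$hap_a) == n_sites(map), n_f1 >= 2)
  lines_used <- unique(c(design$crosses$sire, design$crosses$dam))
  unknown <- setdiff(lines_used, panel$line_ids)
  if (length(unknown) > 0)
    stop("cross references unknown line(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  TT <- n_sites(map)
  pair_key <- cross_pair_key(design)
  f1_truth_entry <- match(unique(pair_key), pair_key)  # first entry per cross

  ids <- character(0); cross <- character(0); gen <- character(0)
  truth <- logical(0)
  geno <- list(); origin <- list()

  # founder haplotype labels: line index * 2 - 1 (hap a) / * 2 (hap b)
  line_idx <- function(l) match(l, panel$line_ids)

  for (e in seq_len(nrow(design$crosses))) {
    cr <- design$crosses[e, ]
    si <- line_idx(cr$sire); di <- line_idx(cr$dam)
    # F1 pool: haplotype 1 is a sire-line gamete, haplotype 2 a dam-line one
    f1 <- lapply(seq_len(n_f1), function(j) {
      s_src <- gamete_source(map); d_src <- gamete_source(map)
      list(h1 = ifelse(s_src == 1L, panel$hap_a[si, ], panel$hap_b[si, ]),
           h2 = ifelse(d_src == 1L, panel$hap_a[di, ], panel$hap_b[di, ]),
           o1 = 2L * si - 2L + s_src, o2 = 2L * di - 2L + d_src)
    })
    n_f1_truth <- if (e %in% f1_truth_entry) design$truth_plan$f1_per_cross
                  else 0
    for (j in seq_len(n_f1_truth)) {
      ids <- c(ids, sprintf("%s_F1_%02d", cr$id, j))
      cross <- c(cross, cr$id); gen <- c(gen, "F1"); truth <- c(truth, TRUE)
      geno[[length(geno) + 1L]] <- f1[[j]]$h1 + f1[[j]]$h2
      if (keep_origin)
        origin[[length(origin) + 1L]] <- rbind(f1[[j]]$o1, f1[[j]]$o2)
    }
    n_f2_truth <- if (e == design$truth_plan$extra_f2_cross)
      design$truth_plan$extra_f2 else 0
    for (j in seq_len(cr$n_f2)) {
      par <- sample(n_f1, 2)  # two distinct F1 parents
      g <- lapply(par, function(p) {
        src <- gamete_source(map)
        list(h = ifelse(src == 1L, f1[[p]]$h1, f1[[p]]$h2),
             o = ifelse(src == 1L, f1[[p]]$o1, f1[[p]]$o2))
      })
      ids <- c(ids, sprintf("%s_F2_%04d", cr$id, j))
      cross <- c(cross, cr$id); gen <- c(gen, "F2")
      truth <- c(truth, j <= n_f2_truth)
      geno[[length(geno) + 1L]] <- g[[1]]$h + g[[2]]$h
      if (keep_origin)
        origin[[length(origin) + 1L]] <- rbind(g[[1]]$o, g[[2]]$o)
    }
  }

  truth_geno <- do.call(rbind, geno)
  dimnames(truth_geno) <- list(ids, NULL)
  out <- list(samples = data.frame(sample_id = ids, cross = cross,
                                   generation = gen, is_truth = truth,
                                   stringsAsFactors = FALSE),
              truth_geno = truth_geno,
              ref_count = NULL, alt_count = NULL, base_error = NA_real_)
  if (keep_origin) out$origin <- origin
  structure(out, class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$samples), "samples (",
      sum(x$samples$is_truth), "truth ),",
      ncol(x$truth_geno), "sites,",
      if (is.null(x$ref_count)) "no reads simulated yet"
      else sprintf("mean depth %.2fx", mean(x$ref_count + x$alt_count)),
      "\n")
  invisible(x)
}

n_samples <- function(cohort) nrow(cohort$samples)
truth_idx <- function(cohort) which(cohort$samples$is_truth)
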