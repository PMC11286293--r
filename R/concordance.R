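#' Squared Pearson correlation with zero-variance guard
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return `cor(x, y)^2`, or `NA` when either vector is constant.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) return(undefined_value())
  cor(x, y)^2
}

#' Per-sample imputation concordance
#'
#' For each evaluated sample, the squared Pearson correlation between its
#' imputed dosages and its true genotypes across all sites, plus the
#' unweighted mean across samples (the summary used to compare imputation
#' runs).
#'
#' @param dosage Samples x sites matrix of imputed dosages.
#' @param truth Matching matrix of true genotypes.
#' @return List with `per_sample_r2` (named by sample when dimnames are
#'   present) and `mean_r2` (mean over the defined values).
#' @export
per_sample_concordance <- function(dosage, truth) {
  dosage <- as.matrix(dosage); truth <- as.matrix(truth)
  stopifnot(all(dim(dosage) == dim(truth)), nrow(dosage) >= 1)
  r2 <- vapply(seq_len(nrow(dosage)), function(i)
    pearson_r2(dosage[i, ], truth[i, ]), numeric(1))
  names(r2) <- rownames(dosage)
  list(per_sample_r2 = r2, mean_r2 = mean(r2, na.rm = TRUE))
}

#' Minor allele frequency of each site from a genotype matrix
#'
#' @param geno Samples x sites genotype matrix (0/1/2).
#' @return Per-site MAF in \[0, 0.5\].
#' @export
observed_maf <- function(geno) {
  f <- colMeans(as.matrix(geno)) / 2
  pmin(f, 1 - f)
}

#' MAF-binned imputation concordance
#'
#' Sites are assigned to minor allele frequency bins of width 0.05
#' (`[0, 0.05), [0.05, 0.10), ..., [0.45, 0.5]`; the last bin is closed).
#' Within a bin, all (site, sample) dosage/truth pairs are pooled into a
#' single squared Pearson correlation, and the bin is labelled with the
#' mean observed MAF of its member sites.
#'
#' @param dosage Samples x sites matrix of imputed dosages.
#' @param truth Matching matrix of true genotypes.
#' @param maf Per-site minor allele frequency in \[0, 0.5\] (see
#'   [observed_maf()]; computed from the truth samples' genotypes by
#'   default in the pipeline).
#' @return Data frame with one row per bin: `lower`, `upper`, `mean_maf`,
#'   `r2` (`NA` for empty or degenerate bins) and `n_snps`.
#' @export
maf_binned_concordance <- function(dosage, truth, maf) {
  dosage <- as.matrix(dosage); truth <- as.matrix(truth)
  stopifnot(all(dim(dosage) == dim(truth)), length(maf) == ncol(dosage))
  if (any(maf < 0)) stop("MAF cannot be negative")
  if (any(maf > 0.5)) stop("MAF cannot exceed 0.5")
  bin <- pmin(floor(maf / 0.05), 9) + 1
  out <- data.frame(lower = seq(0, 0.45, by = 0.05),
                    upper = seq(0.05, 0.5, by = 0.05),
                    mean_maf = NA_real_, r2 = NA_real_, n_snps = 0L)
  for (b in seq_len(10)) {
    s <- which(bin == b)
    out$n_snps[b] <- length(s)
    if (length(s) == 0) next
    out$mean_maf[b] <- mean(maf[s])
    x <- as.vector(dosage[, s, drop = FALSE])
    y <- as.vector(truth[, s, drop = FALSE])
    if (length(x) >= 2) out$r2[b] <- pearson_r2(x, y)
  }
  out
}
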