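#' Simulate a panel of inbred founder lines
#'
#' Each line is almost fully homozygous: at every site a population
#' alternate-allele frequency is drawn from a uniform prior and the line's
#' consensus allele is sampled from it; a fraction `residual_het` of
#' (line, site) pairs is then made heterozygous by flipping the second
#' haplotype.  Sites at which the whole panel would be monomorphic are
#' redrawn so that every site is polymorphic across the panel.
#'
#' @param map A `genome_map`.
#' @param n_lines Number of founder lines (>= 2).
#' @param residual_het Fraction of (line, site) pairs left heterozygous,
#'   in \[0, 0.5).  Inbred lines are never perfectly homozygous; this models
#'   the residual variability they retain.
#' @param seed Optional integer seed.
#' @param freq_range Range of the uniform alternate-allele frequency prior.
#' @param line_ids Labels for the lines; defaults to `line_1`, `line_2`, ...
#'
#' @return A `founder_panel`: list with `line_ids`, `hap_a` and `hap_b`
#'   (lines x sites 0/1 matrices), `freq` (the per-site population
#'   frequency used) and `residual_het`.
#' @export
simulate_founders <- function(map, n_lines = 8, residual_het = 0.01,
                              seed = NULL, freq_range = c(0.05, 0.95),
                              line_ids = NULL) {
  stopifnot(inherits(map, "genome_map"))
  if (n_lines < 2) stop("need at least 2 founder lines")
  if (residual_het < 0 || residual_het >= 0.5)
    stop("residual_het must be in [0, 0.5)")
  if (is.null(line_ids)) line_ids <- paste0("line_", seq_len(n_lines))
  stopifnot(length(line_ids) == n_lines, !anyDuplicated(line_ids))
  if (!is.null(seed)) set.seed(seed)

  TT <- n_sites(map)
  # the heterozygosity mask is drawn once and never conditioned on, so the
  # realized het fraction is exactly Binomial(residual_het)
  het <- matrix(rbinom(n_lines * TT, 1, residual_het) == 1, nrow = n_lines)
  draw_consensus <- function(n) {
    freq <- runif(n, freq_range[1], freq_range[2])
    cons <- matrix(rbinom(n_lines * n, 1, rep(freq, each = n_lines)),
                   nrow = n_lines)
    list(freq = freq, cons = cons)
  }
  d <- draw_consensus(TT)
  # enforce panel-wide polymorphism by redrawing the consensus alleles of
  # monomorphic columns (columns with a heterozygous line are already
  # polymorphic, so only all-homozygous columns can need a redraw)
  any_het <- colSums(het) > 0
  mono <- integer(0)
  for (attempt in 1:1000) {
    mono <- which(!any_het &
                    apply(d$cons == d$cons[1, ][col(d$cons)], 2, all))
    if (length(mono) == 0) break
    r <- draw_consensus(length(mono))
    d$freq[mono] <- r$freq
    d$cons[, mono] <- r$cons
  }
  if (length(mono) > 0) {
    # vanishingly unlikely; flip one allele rather than loop forever
    d$cons[1, mono] <- 1L - d$cons[1, mono]
  }
  hap_a <- d$cons
  hap_b <- ifelse(het, 1L - d$cons, d$cons)
  dimnames(hap_a) <- dimnames(hap_b) <- list(line_ids, NULL)
  structure(list(line_ids = line_ids, hap_a = hap_a, hap_b = hap_b,
                 freq = d$freq, residual_het = residual_het),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", length(x$line_ids), "lines,",
      ncol(x$hap_a), "sites, residual het",
      format(mean(x$hap_a != x$hap_b), digits = 3), "\n")
  invisible(x)
}
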