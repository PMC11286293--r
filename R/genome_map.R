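#' Build a genome map with uniformly placed SNP sites
#'
#' Draws biallelic SNP positions uniformly without replacement along each
#' chromosome and attaches a uniform genetic map expressed as a
#' recombination rate in cM/Mb.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp (recycled across chromosomes).
#' @param n_sites Number of SNP sites per chromosome.
#' @param exp_rate Recombination rate in cM/Mb.
#' @param seed Optional integer seed; when given, the map is reproducible.
#'
#' @return An object of class `genome_map`: a list with `chromosomes`
#'   (data frame of name and length), `sites` (data frame of chrom and pos,
#'   ordered, 1-based) and `exp_rate`.
#' @examples
#' map <- make_genome_map(1, 5e6, 200, exp_rate = 2, seed = 1)
#' @export
make_genome_map <- function(n_chrom = 1, chrom_len = 5e6, n_sites = 2000,
                            exp_rate = 2, seed = NULL) {
  stopifnot(n_chrom >= 1, exp_rate >= 0)
  chrom_len <- rep_len(chrom_len, n_chrom)
  n_sites <- rep_len(n_sites, n_chrom)
  if (any(n_sites < 2))
    stop("need at least 2 sites per chromosome")
  if (any(n_sites > chrom_len))
    stop("cannot place more sites than base pairs on a chromosome")
  if (!is.null(seed)) set.seed(seed)
  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = chrom_len, stringsAsFactors = FALSE)
  sites <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    pos <- sort(sample.int(chrom_len[i], n_sites[i]))
    data.frame(chrom = chroms$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  structure(list(chromosomes = chroms, sites = sites, exp_rate = exp_rate),
            class = "genome_map")
}

n_sites <- function(map) nrow(map$sites)

#' Restrict a genome map to a subset of its sites
#'
#' @param map A `genome_map`.
#' @param idx Integer indices (into the ordered site table) to retain.
#' @return A `genome_map` over the retained sites.
#' @export
subset_map <- function(map, idx) {
  stopifnot(inherits(map, "genome_map"))
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) < 1 || min(idx) < 1 || max(idx) > n_sites(map))
    stop("site indices out of range")
  map$sites <- map$sites[idx, , drop = FALSE]
  rownames(map$sites) <- NULL
  map
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$sites), "SNP sites,", x$exp_rate, "cM/Mb\n")
  invisible(x)
}
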