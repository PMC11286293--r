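#' Write genotypes, read counts or imputation output as VCF
#'
#' Produces a minimal VCFv4.2 file (1-based positions, biallelic SNPs
#' with placeholder REF/ALT alleles A/T) holding any combination of GT
#' (hard genotypes, unphased), AD (ref,alt read counts), DS (dosage) and
#' GP (genotype posteriors) FORMAT fields, plus an `INFO_SCORE` INFO
#' field when given.
#'
#' @param path Output file path (plain text).
#' @param map A `genome_map` providing CHROM/POS for every site.
#' @param sample_ids Sample names, in row order of the matrices.
#' @param geno Optional samples x sites 0/1/2 genotype matrix (GT).
#' @param ref_count,alt_count Optional samples x sites read-count
#'   matrices (AD, written as "ref,alt").
#' @param dosage Optional samples x sites dosage matrix (DS).
#' @param gp Optional samples x sites x 3 genotype posterior array (GP).
#' @param info_score Optional per-site info score (INFO field).
#' @param digits Significant digits for DS/GP/INFO_SCORE.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, map, sample_ids, geno = NULL, ref_count = NULL,
                      alt_count = NULL, dosage = NULL, gp = NULL,
                      info_score = NULL, digits = 4) {
  stopifnot(inherits(map, "genome_map"))
  TT <- n_sites(map)
  N <- length(sample_ids)
  has_ad <- !is.null(ref_count)
  if (has_ad) stopifnot(!is.null(alt_count))
  fmt <- c(if (!is.null(geno)) "GT", if (has_ad) "AD",
           if (!is.null(dosage)) "DS", if (!is.null(gp)) "GP")
  if (length(fmt) == 0) stop("nothing to write")

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crossimpute",
    sprintf("##contig=<ID=%s,length=%d>", map$chromosomes$name,
            map$chromosomes$length),
    if (!is.null(info_score))
      paste0("##INFO=<ID=INFO_SCORE,Number=1,Type=Float,",
             "Description=\"Imputation info score\">"),
    if (!is.null(geno))
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ad)
      paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
             "Description=\"Allelic depths (ref,alt)\">"),
    if (!is.null(dosage))
      paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
             "Description=\"Alternate allele dosage\">"),
    if (!is.null(gp))
      paste0("##FORMAT=<ID=GP,Number=G,Type=Float,",
             "Description=\"Genotype posterior probabilities\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))

  gt_code <- c("0/0", "0/1", "1/1")
  num <- function(x) formatC(x, digits = digits, format = "g")
  cells <- matrix("", nrow = TT, ncol = N)
  for (i in seq_len(N)) {
    parts <- list()
    if (!is.null(geno)) parts$gt <- gt_code[geno[i, ] + 1L]
    if (has_ad) parts$ad <- paste0(ref_count[i, ], ",", alt_count[i, ])
    if (!is.null(dosage)) parts$ds <- num(dosage[i, ])
    if (!is.null(gp)) parts$gp <- paste(num(gp[i, , 1]), num(gp[i, , 2]),
                                        num(gp[i, , 3]), sep = ",")
    cells[, i] <- do.call(paste, c(parts, sep = ":"))
  }
  info <- if (!is.null(info_score))
    paste0("INFO_SCORE=", ifelse(is.na(info_score), ".",
                                 num(info_score))) else "."
  body <- paste(map$sites$chrom, map$sites$pos, ".", "A", "T", ".", "PASS",
                info, paste(fmt, collapse = ":"),
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into genotype and read-count tables
#'
#' Loads a VCF (via `vcfR`), keeps biallelic SNP records only
#' (multiallelic or non-SNP records are skipped with a message), orders
#' sites by (chrom, pos), and extracts whichever of GT, AD, DS and GP are
#' present.  A file carrying neither GT nor AD is rejected.
#'
#' @param path VCF file path.
#' @return List with `sites` (data frame: chrom, pos, ref, alt,
#'   info_score), `sample_ids`, and samples x sites matrices `gt` (0/1/2,
#'   NA for missing), `ad_ref`, `ad_alt`, `dosage` for the fields
#'   present.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ok <- !is.na(fix$REF) & !is.na(fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1 & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  if (any(!ok))
    message("read_vcf: skipped ", sum(!ok),
            " multiallelic or non-SNP record(s)")
  if (!any(ok)) stop("no biallelic SNP records in ", path)
  v <- v[ok, ]
  fix <- fix[ok, , drop = FALSE]
  pos <- as.integer(fix$POS)
  ord <- order(fix$CHROM, pos)
  v <- v[ord, ]
  fix <- fix[ord, , drop = FALSE]
  pos <- pos[ord]

  fmt <- strsplit(v@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
  if (!any(c("GT", "AD") %in% fmt))
    stop("VCF carries neither GT nor AD FORMAT fields")
  out <- list()
  out$sites <- data.frame(chrom = fix$CHROM, pos = pos, ref = fix$REF,
                          alt = fix$ALT, stringsAsFactors = FALSE)
  is_info <- grepl("INFO_SCORE=", fix$INFO)
  if (any(is_info)) {
    val <- sub(".*INFO_SCORE=([^;]*).*", "\\1", fix$INFO)
    out$sites$info_score <- suppressWarnings(as.numeric(val))
  }
  if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    conv <- matrix(NA_integer_, nrow(gt), ncol(gt))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    conv[clean == "0/0"] <- 0L
    conv[clean %in% c("0/1", "1/0")] <- 1L
    conv[clean == "1/1"] <- 2L
    out$gt <- t(conv)
    dimnames(out$gt) <- list(colnames(gt), NULL)
  }
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v, element = "AD")
    refc <- vapply(strsplit(ad, ",", fixed = TRUE), function(x)
      as.integer(x[1]), integer(1))
    altc <- vapply(strsplit(ad, ",", fixed = TRUE), function(x)
      as.integer(x[2]), integer(1))
    out$ad_ref <- t(matrix(refc, nrow(ad), ncol(ad)))
    out$ad_alt <- t(matrix(altc, nrow(ad), ncol(ad)))
    dimnames(out$ad_ref) <- dimnames(out$ad_alt) <-
      list(colnames(ad), NULL)
  }
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS")
    out$dosage <- t(matrix(as.numeric(ds), nrow(ds), ncol(ds)))
    dimnames(out$dosage) <- list(colnames(ds), NULL)
  }
  out$sample_ids <- colnames(v@gt)[-1]
  out
}

#' Write the per-sample metadata table of a cohort
#'
#' @param path Output TSV path.
#' @param cohort A `sim_cohort`.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(path, cohort) {
  write.table(cohort$samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
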