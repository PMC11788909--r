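#' VariantTable: the filtering substrate
#'
#' A light container for the fields of a VCF that the SNP filtering cascade
#' and relatedness estimation use: per-locus alleles and site mapping
#' quality, and per-genotype code / depth / genotype quality matrices
#' (loci in rows, individuals in columns).  Genotype codes count copies of
#' the alternate allele (`0`, `1`, `2`, `NA` = missing).
#'
#' @param loci `data.frame` with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt` (comma-separated when multiallelic), `mapq` (`NA` when the
#'   annotation is absent).
#' @param geno integer matrix of genotype codes, loci x individuals.
#' @param dp,gq numeric matrices of read depth and genotype quality with the
#'   same shape as `geno`; `NULL` when the annotation is absent.
#' @param individual_ids character vector naming the genotype columns.
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(loci, geno, dp = NULL, gq = NULL, individual_ids) {
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "id", "ref", "alt", "mapq") %in% names(loci)),
            is.matrix(geno), nrow(geno) == nrow(loci),
            ncol(geno) == length(individual_ids))
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids")
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) stop("genotype codes must be in {0, 1, 2, NA}")
  for (m in list(dp, gq)) {
    if (!is.null(m)) stopifnot(is.matrix(m), all(dim(m) == dim(geno)))
  }
  if (!is.null(dp) && any(dp < 0, na.rm = TRUE)) stop("DP must be >= 0")
  if (!is.null(gq) && any(gq < 0, na.rm = TRUE)) stop("GQ must be >= 0")
  if (any(loci$ref == loci$alt)) stop("ref allele equals alt allele")
  dimnames(geno) <- list(loci$id, individual_ids)
  if (!is.null(dp)) dimnames(dp) <- dimnames(geno)
  if (!is.null(gq)) dimnames(gq) <- dimnames(geno)
  rownames(loci) <- NULL
  structure(list(loci = loci, geno = geno, dp = dp, gq = gq,
                 individual_ids = individual_ids),
            class = "variant_table")
}

#' @exportS3Method print variant_table
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$loci), "loci x",
      length(x$individual_ids), "individuals\n")
  cat("  annotations:",
      paste(c("GT", if (!is.null(x$dp)) "DP", if (!is.null(x$gq)) "GQ",
              if (any(!is.na(x$loci$mapq))) "MQ"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$loci), length(x$individual_ids))

# subset a variant_table by locus index, keeping all matrices aligned
vt_subset <- function(x, keep) {
  structure(list(
    loci = x$loci[keep, , drop = FALSE],
    geno = x$geno[keep, , drop = FALSE],
    dp = if (is.null(x$dp)) NULL else x$dp[keep, , drop = FALSE],
    gq = if (is.null(x$gq)) NULL else x$gq[keep, , drop = FALSE],
    individual_ids = x$individual_ids), class = "variant_table")
}

#' Extract the genotype matrix (individuals x loci)
#'
#' @param x a `variant_table`.
#' @return integer matrix of codes with individuals in rows, ready for
#'   [vanraden_grm()].
#' @export
genotype_matrix <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  t(x$geno)
}
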