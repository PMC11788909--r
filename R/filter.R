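# SNP filtering cascade.
#
# The cascade mirrors the practical VCFtools-style pipeline used to clean
# raw target-capture variant calls: indels and multiallelic records first,
# then minor allele frequency, missingness, genotype quality, mapping
# quality, site depth bounds relative to the mean of the depth
# distribution, and (optionally) excess heterozygosity.  Per-rule removal
# counts are defined with respect to this fixed order.

#' Filtering configuration
#'
#' @param drop_indels,drop_multiallelic drop indel / multiallelic records.
#' @param maf_min minor-allele-frequency threshold: loci with `MAF < maf_min`
#'   are removed; `0` removes monomorphic loci only.
#' @param max_missing_fraction loci whose missing-genotype fraction exceeds
#'   this are removed (`0` = no missing genotypes allowed).
#' @param gq_min genotype-quality threshold: genotypes must satisfy
#'   `GQ > gq_min` (strict, Phred scale).
#' @param mapq_min site mapping-quality threshold (`MapQ > mapq_min`, strict).
#' @param min_depth_factor,max_depth_factor per-site mean depth must lie in
#'   `[min_depth_factor, max_depth_factor] * (global mean depth)`; the global
#'   mean is the mean over per-site mean depths of the input table.
#' @param min_dp,max_dp explicit depth bounds; when given they override the
#'   factor-based bounds (useful for idempotent re-filtering).
#' @param het_max observed-heterozygosity ceiling (0.5 is the theoretical
#'   maximum for a biallelic locus); `NA` disables the rule.
#' @param small_sample_mode with very few individuals (e.g., a single family
#'   of five) allele frequencies are too unstable for a MAF cutoff, so only
#'   monomorphic loci are removed and no missing genotypes are tolerated.
#' @param gq_mode `"mask"` (default) sets failing genotypes to missing and
#'   re-applies the missingness rule; `"site"` drops a site whose non-missing
#'   genotypes include any failing GQ.
#' @param depth_mode `"site"` (default) filters on per-site mean depth;
#'   `"genotype"` masks out-of-bounds genotypes to missing and re-applies the
#'   missingness rule.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(drop_indels = TRUE,
                          drop_multiallelic = TRUE,
                          maf_min = 0.05,
                          max_missing_fraction = 0.1,
                          gq_min = 16,
                          mapq_min = 40,
                          min_depth_factor = 0.5,
                          max_depth_factor = 2.0,
                          min_dp = NULL,
                          max_dp = NULL,
                          het_max = NA_real_,
                          small_sample_mode = FALSE,
                          gq_mode = c("mask", "site"),
                          depth_mode = c("site", "genotype")) {
  gq_mode <- match.arg(gq_mode)
  depth_mode <- match.arg(depth_mode)
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_depth_factor > 0, max_depth_factor > 0,
            min_depth_factor < max_depth_factor,
            is.na(het_max) || (het_max >= 0 && het_max <= 1))
  structure(list(drop_indels = drop_indels,
                 drop_multiallelic = drop_multiallelic,
                 maf_min = maf_min,
                 max_missing_fraction = max_missing_fraction,
                 gq_min = gq_min, mapq_min = mapq_min,
                 min_depth_factor = min_depth_factor,
                 max_depth_factor = max_depth_factor,
                 min_dp = min_dp, max_dp = max_dp,
                 het_max = het_max,
                 small_sample_mode = small_sample_mode,
                 gq_mode = gq_mode, depth_mode = depth_mode),
            class = "filter_config")
}

#' Species-preset filter configurations
#'
#' Tightened presets of the kind used when relatedness estimates from the
#' default cascade remain noisy: a higher MAF cutoff and an excess
#' heterozygosity ceiling (`maf_min = 0.2, het_max = 0.5`), or an
#' intermediate MAF cutoff (`maf_min = 0.1`).
#'
#' @param preset one of `"default"`, `"maf02_het"`, `"maf01"`.
#' @param ... further arguments passed to [filter_config()].
#' @return a `filter_config`.
#' @export
filter_preset <- function(preset = c("default", "maf02_het", "maf01"), ...) {
  preset <- match.arg(preset)
  switch(preset,
    default = filter_config(...),
    maf02_het = filter_config(maf_min = 0.2, het_max = 0.5, ...),
    maf01 = filter_config(maf_min = 0.1, ...))
}

#' Minor allele frequency of one locus
#'
#' `MAF = min(p, 1 - p)` with `p = sum(codes) / (2 * non-missing count)`.
#'
#' @param codes integer vector of genotype codes (`0/1/2/NA`).
#' @return the minor allele frequency.
#' @export
#' @examples
#' minor_allele_frequency(c(0, 0, 1))   # 1/6
minor_allele_frequency <- function(codes) {
  n <- sum(!is.na(codes))
  if (n == 0L) stop("all genotypes missing")
  p <- sum(codes, na.rm = TRUE) / (2 * n)
  min(p, 1 - p)
}

#' Observed heterozygosity of one locus
#'
#' Fraction of non-missing genotypes that are heterozygous (code 1).  For a
#' biallelic locus the theoretical expectation never exceeds
#' `max_p 2p(1-p) = 0.5`; loci above that ceiling usually indicate collapsed
#' paralogs or mis-mapping.
#'
#' @param codes integer vector of genotype codes (`0/1/2/NA`).
#' @return observed heterozygosity in `[0, 1]`.
#' @export
observed_heterozygosity <- function(codes) {
  n <- sum(!is.na(codes))
  if (n == 0L) stop("all genotypes missing")
  sum(codes == 1L, na.rm = TRUE) / n
}

#' Theoretical maximum expected heterozygosity of a biallelic locus
#'
#' The Hardy-Weinberg heterozygote frequency `2p(1-p)` is maximised at
#' `p = 0.5`, giving 0.5.  This constant anchors the excess-heterozygosity
#' rule of the cascade.
#'
#' @return 0.5
#' @export
max_expected_heterozygosity <- function() {
  2 * 0.5 * (1 - 0.5)
}

#' Per-site and global mean read depth
#'
#' @param table a [variant_table()] with DP.
#' @param config a [filter_config()]; supplies the depth factors.
#' @return a list with `site_mean` (per-locus mean DP over non-missing
#'   genotypes), `global_mean` (mean of the per-locus means), and the
#'   derived `min_dp` / `max_dp` thresholds.
#' @export
site_mean_depth <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "variant_table"))
  if (nrow(table$loci) == 0L) stop("empty variant table")
  if (is.null(table$dp)) stop("variant table carries no DP annotation")
  dp <- table$dp
  dp[is.na(table$geno)] <- NA
  site_mean <- rowMeans(dp, na.rm = TRUE)
  global_mean <- mean(site_mean)
  list(site_mean = site_mean, global_mean = global_mean,
       min_dp = if (is.null(config$min_dp))
         config$min_depth_factor * global_mean else config$min_dp,
       max_dp = if (is.null(config$max_dp))
         config$max_depth_factor * global_mean else config$max_dp)
}

#' Apply the SNP filtering cascade
#'
#' Rules are applied in a fixed order: (1) indels, (2) multiallelic records,
#' (3) MAF, (4) missingness, (5) GQ (genotype masking followed by the
#' missingness rule, or site-level, per `gq_mode`), (6) MapQ, (7) site mean
#' depth within `[minDP, maxDP]`, (8) excess heterozygosity (when `het_max`
#' is set).  Depth thresholds are derived from the mean of the per-site mean
#' depths of the *input* table (before any removal) unless pinned via
#' `min_dp` / `max_dp`.  In `small_sample_mode` the MAF rule removes
#' monomorphic loci only and the missingness rule tolerates no missing
#' genotypes.
#'
#' @param table a [variant_table()].
#' @param config a [filter_config()].
#' @return a list of class `filter_result`: `table` (the filtered
#'   `variant_table`, with GQ-masked genotypes set to missing when
#'   `gq_mode = "mask"`), and `report` (a `data.frame` of per-rule removal
#'   counts in application order, with attributes `loci_in`, `loci_out`,
#'   `min_dp`, `max_dp`).
#' @export
apply_filters <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "variant_table"),
            inherits(config, "filter_config"))
  n_in <- nrow(table$loci)
  removed <- c(indel = 0L, multiallelic = 0L, maf = 0L, missing = 0L,
               gq = 0L, mapq = 0L, depth = 0L, heterozygosity = 0L)

  # depth thresholds from the raw input table
  dpth <- if (!is.null(table$dp) && n_in > 0L) site_mean_depth(table, config)
          else NULL

  max_miss <- if (config$small_sample_mode) 0 else config$max_missing_fraction
  miss_ok <- function(codes) {
    mean(is.na(codes)) <= max_miss && any(!is.na(codes))
  }

  keep <- rep(TRUE, n_in)
  drop_rule <- function(keep, fail, rule) {
    fail <- keep & fail
    removed[rule] <<- sum(fail)
    keep & !fail
  }

  is_indel <- nchar(table$loci$ref) > 1L |
    vapply(strsplit(table$loci$alt, ","), function(a) any(nchar(a) > 1L),
           TRUE)
  if (config$drop_indels) keep <- drop_rule(keep, is_indel, "indel")

  is_multi <- vapply(strsplit(table$loci$alt, ","), length, 1L) > 1L
  if (config$drop_multiallelic) keep <- drop_rule(keep, is_multi, "multiallelic")

  maf <- apply(table$geno, 1L, function(g)
    if (all(is.na(g))) NA_real_ else minor_allele_frequency(g))
  maf_fail <- if (config$small_sample_mode || config$maf_min == 0)
    !is.na(maf) & maf == 0 else !is.na(maf) & maf < config$maf_min
  maf_fail <- maf_fail | is.na(maf)
  keep <- drop_rule(keep, maf_fail, "maf")

  miss_fail <- !apply(table$geno, 1L, miss_ok)
  keep <- drop_rule(keep, miss_fail, "missing")

  # GQ rule
  geno <- table$geno
  if (!is.null(table$gq)) {
    if (config$gq_mode == "mask") {
      masked <- geno
      masked[!is.na(geno) & !(table$gq > config$gq_min)] <- NA_integer_
      gq_fail <- !apply(masked, 1L, miss_ok)
      geno <- masked
    } else {
      gq_fail <- apply(!is.na(geno) & !(table$gq > config$gq_min), 1L, any)
    }
    keep <- drop_rule(keep, gq_fail, "gq")
  }

  if (any(!is.na(table$loci$mapq))) {
    mq_fail <- !is.na(table$loci$mapq) & !(table$loci$mapq > config$mapq_min)
    keep <- drop_rule(keep, mq_fail, "mapq")
  }

  if (!is.null(dpth)) {
    if (config$depth_mode == "site") {
      dp_fail <- dpth$site_mean < dpth$min_dp | dpth$site_mean > dpth$max_dp
      keep <- drop_rule(keep, dp_fail, "depth")
    } else {
      masked <- geno
      out <- !is.na(table$dp) &
        (table$dp < dpth$min_dp | table$dp > dpth$max_dp)
      masked[out] <- NA_integer_
      dp_fail <- !apply(masked, 1L, miss_ok)
      geno <- masked
      keep <- drop_rule(keep, dp_fail, "depth")
    }
  }

  if (!is.na(config$het_max)) {
    het <- apply(geno, 1L, function(g)
      if (all(is.na(g))) NA_real_ else observed_heterozygosity(g))
    het_fail <- is.na(het) | het > config$het_max
    keep <- drop_rule(keep, het_fail, "heterozygosity")
  }

  out <- table
  out$geno <- geno
  dimnames(out$geno) <- dimnames(table$geno)
  out <- vt_subset(out, keep)

  report <- data.frame(rule = names(removed), removed = unname(removed),
                       stringsAsFactors = FALSE)
  attr(report, "loci_in") <- n_in
  attr(report, "loci_out") <- sum(keep)
  attr(report, "min_dp") <- if (is.null(dpth)) NA_real_ else dpth$min_dp
  attr(report, "max_dp") <- if (is.null(dpth)) NA_real_ else dpth$max_dp
  stopifnot(n_in - sum(removed) == sum(keep))
  structure(list(table = out, report = report), class = "filter_result")
}

#' @exportS3Method print filter_result
print.filter_result <- function(x, ...) {
  cat("SNP filtering:", attr(x$report, "loci_in"), "loci in,",
      attr(x$report, "loci_out"), "retained\n")
  for (i in seq_len(nrow(x$report)))
    cat(sprintf("  %-15s removed %d\n", x$report$rule[i], x$report$removed[i]))
  invisible(x)
}
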