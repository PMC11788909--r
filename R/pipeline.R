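# End-to-end pipeline driver: simulate -> consensus -> filter -> relate ->
# correct -> design-primers -> ispcr, with every intermediate written to
# disk so each stage can also be rerun standalone from files.

#' Run the full marker-development pipeline on simulated data
#'
#' Executes every stage in order and writes all artefacts into `out_dir`:
#' pedigree and truth tables, raw VCF and per-gene alignments, the
#' consensus reference, the filtered VCF with its report, the GRM, PCA
#' coordinates, family summaries and grouping similarity, the corrected
#' pedigree with a before/after report, designed primers, and the
#' in-silico PCR summary (screened against the true gene templates, which
#' play the role of the species' genome).  A provenance record (config
#' echo, seed, package version) is written alongside.  Outputs are a pure
#' function of the configuration: rerunning with the same seed reproduces
#' every file byte for byte.
#'
#' @param out_dir output directory (created if absent).
#' @param config a [sim_config()].
#' @param filter_cfg a [filter_config()].
#' @param correction_cfg a [correction_config()].
#' @param constraints a [primer_constraints()].
#' @param n_primer_pairs primer pairs to design (default 30).
#' @param mismatch_pcts in-silico PCR mismatch allowances (default 10 and 0).
#' @return invisibly, a list with the key in-memory results (`sim`, `grm`,
#'   `correction`, `primers`, `ispcr`, ...) and `files` (named vector of
#'   artefact paths).
#' @export
run_pipeline <- function(out_dir,
                         config = sim_config(),
                         filter_cfg = filter_config(),
                         correction_cfg = correction_config(),
                         constraints = primer_constraints(),
                         n_primer_pairs = 30L,
                         mismatch_pcts = c(10, 0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)

  # 1. simulate
  ped <- simulate_pedigree(config)
  sim <- simulate_genotypes(ped, config)
  alns <- embed_snps_in_genes(sim, config)
  vt <- apply_observation_model(sim, config)
  write_pedigree(ped, path("pedigree.csv"))
  write_tsv(cbind(sim$loci), path("truth_loci.tsv"))
  write_vcf(vt, path("raw.vcf"))
  write_alignments(alns, path("alignments"))
  write_fasta(attr(alns, "templates"), path("true_templates.fasta"))

  # 2. consensus reference
  ref <- build_reference(alns)
  write_fasta(setNames(ref$consensus, ref$gene_id), path("reference.fasta"))
  rep <- attr(ref, "report")
  write_tsv(data.frame(n_genes = rep$n_genes, mean_length = rep$mean_length),
            path("consensus_report.tsv"))

  # 3. filter
  fr <- apply_filters(vt, filter_cfg)
  write_vcf(fr$table, path("filtered.vcf"))
  frep <- fr$report
  frep$loci_in <- attr(frep, "loci_in")
  frep$loci_out <- attr(frep, "loci_out")
  write_tsv(frep, path("filter_report.tsv"))

  # 4. relatedness
  geno <- genotype_matrix(fr$table)
  grm <- vanraden_grm(geno, "sample")
  write_grm(grm, path("grm.tsv"))
  pca <- grm_pca(grm, n_components = min(4L, nrow(geno) - 1L))
  write_tsv(data.frame(individual_id = rownames(pca$coordinates),
                       round(pca$coordinates, 10)),
            path("pca.tsv"))
  fam <- family_mean_relatedness(grm, ped)
  write_tsv(fam, path("family_summary.tsv"))
  sim_groups <- grouping_similarity(pca, ped)
  write_tsv(data.frame(individual_id = names(sim_groups$assigned),
                       pedigree_family = ped$family_id,
                       assigned_family = unname(sim_groups$assigned),
                       similarity = sim_groups$similarity),
            path("grouping.tsv"))

  # 5. pedigree correction
  corr <- correct_pedigree(grm, ped[, c("individual_id", "family_id",
                                        "provenance_id")], correction_cfg)
  write_pedigree(corr$pedigree, path("corrected_pedigree.csv"))
  write_tsv(correction_report(corr), path("correction_report.tsv"))

  # 6. primer design on the consensus reference, retained SNPs only
  snps <- data.frame(gene_id = fr$table$loci$chrom,
                     pos = fr$table$loci$pos,
                     locus_id = fr$table$loci$id, stringsAsFactors = FALSE)
  primers <- design_primers(ref, snps, n_pairs = n_primer_pairs,
                            constraints = constraints,
                            seed = config$seed + 6L)
  write_tsv(primers, path("primers.tsv"))
  write_tsv(attr(primers, "failures"), path("primer_failures.tsv"))

  # 7. in-silico PCR against the true gene templates (the "genome")
  isp <- NULL
  if (nrow(primers) > 0L) {
    isp <- ispcr_summary(primers, attr(alns, "templates"),
                         mismatch_pcts = mismatch_pcts)
    write_tsv(isp, path("ispcr_summary.tsv"))
    pp <- attr(isp, "per_pair")
    write_tsv(data.frame(pair_id = rownames(pp), pp, check.names = FALSE),
              path("ispcr_per_pair.tsv"))
  }

  jsonlite::write_json(
    list(package = "capkin",
         version = as.character(packageVersion("capkin")),
         seed = config$seed,
         sim_config = unclass(config),
         filter_config = unclass(filter_cfg),
         correction_config = unclass(correction_cfg)),
    path("provenance.json"), auto_unbox = TRUE, null = "null", digits = NA)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  invisible(list(pedigree = ped, sim = sim, reference = ref, filtered = fr,
                 grm = grm, pca = pca, family_summary = fam,
                 grouping = sim_groups, correction = corr, primers = primers,
                 ispcr = isp, files = files))
}
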