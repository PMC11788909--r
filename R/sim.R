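# Half-sib family simulator.
#
# Emulates the sampling design used in target-capture marker studies of tree
# breeding material: open-pollinated (half-sib) families nested in
# provenances, each family being offspring of one mother and per-offspring
# unrelated fathers.  Biallelic SNPs are embedded in a few hundred gene-like
# loci and observed through a noisy VCF-level layer (depth, genotype
# quality, genotype error, missingness) that stands in for read mapping and
# variant calling.  Ground truth (true genotypes, gametes, founder allele
# frequencies, gene templates) is retained for validation.
#
# All randomness flows from `config$seed` through fixed per-phase substreams
# (seed + 1 pedigree, + 2 founder frequencies/genotypes, + 3 locus placement,
# + 4 gene templates, + 5 observation layer), so every artefact is a pure
# function of the configuration.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the half-sib simulator.
#'
#' @param n_provenances number of provenances (seed sources).
#' @param families_per_provenance half-sib families sampled per provenance.
#' @param offspring_per_family genotyped offspring per family (field studies
#'   of this kind typically sample five).
#' @param n_genes number of gene-like loci carrying the SNPs.
#' @param gene_length_bp length of each gene template, in bp.
#' @param n_snps total number of biallelic SNPs across all genes.
#' @param maf_min lower bound of the founder minor-allele-frequency
#'   distribution; founder frequencies are drawn from
#'   `Uniform(maf_min, 0.5)` per locus.
#' @param genotype_error_rate probability that an observed genotype is
#'   flipped to a random different code.
#' @param missing_rate probability that an observed genotype is missing.
#' @param mean_depth mean per-genotype read depth (negative binomial).
#' @param depth_dispersion negative-binomial size parameter; smaller values
#'   give a more overdispersed depth distribution.
#' @param mapq_mean mean per-site mapping quality.
#' @param fathers_per_provenance optional size of a shared father pool per
#'   provenance.  The default `NULL` draws a new unrelated father for every
#'   offspring (pure half-sib families, within-family expected relatedness
#'   exactly 0.25); a finite pool induces additional relatedness between
#'   families of the same provenance.
#' @param seed integer master seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_provenances = 1, families_per_provenance = 2, seed = 1)
sim_config <- function(n_provenances = 2,
                       families_per_provenance = 2,
                       offspring_per_family = 5,
                       n_genes = 100,
                       gene_length_bp = 800,
                       n_snps = 500,
                       maf_min = 0.05,
                       genotype_error_rate = 0.005,
                       missing_rate = 0.02,
                       mean_depth = 30,
                       depth_dispersion = 5,
                       mapq_mean = 60,
                       fathers_per_provenance = NULL,
                       seed = 1L) {
  cfg <- list(
    n_provenances = as.integer(n_provenances),
    families_per_provenance = as.integer(families_per_provenance),
    offspring_per_family = as.integer(offspring_per_family),
    n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    n_snps = as.integer(n_snps),
    maf_min = maf_min,
    genotype_error_rate = genotype_error_rate,
    missing_rate = missing_rate,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    mapq_mean = mapq_mean,
    fathers_per_provenance = if (is.null(fathers_per_provenance)) NULL
                             else as.integer(fathers_per_provenance),
    seed = as.integer(seed)
  )
  counts <- c("n_provenances", "families_per_provenance",
              "offspring_per_family", "n_genes", "gene_length_bp", "n_snps")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("'", f, "' must be a count >= 1")
  }
  for (f in c("genotype_error_rate", "missing_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be a probability in [0, 1]")
  }
  if (cfg$maf_min <= 0 || cfg$maf_min > 0.5)
    stop("'maf_min' must lie in (0, 0.5]")
  if (cfg$mean_depth <= 0 || cfg$depth_dispersion <= 0)
    stop("'mean_depth' and 'depth_dispersion' must be positive")
  if (!is.null(cfg$fathers_per_provenance) && cfg$fathers_per_provenance < 1L)
    stop("'fathers_per_provenance' must be NULL or >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a half-sib pedigree
#'
#' Families are nested in provenances; all offspring of a family share one
#' mother, and each offspring has its own father (unless
#' `fathers_per_provenance` specifies a shared pool).
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `individual_id`, `family_id`,
#'   `provenance_id`, `mother_id`, `father_id` (one row per offspring).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  rows <- list()
  for (p in seq_len(config$n_provenances)) {
    prov <- sprintf("P%02d", p)
    pool <- if (!is.null(config$fathers_per_provenance))
      sprintf("%s_D%03d", prov, seq_len(config$fathers_per_provenance))
    for (f in seq_len(config$families_per_provenance)) {
      fam <- sprintf("%s_F%02d", prov, f)
      mother <- paste0(fam, "_M")
      for (o in seq_len(config$offspring_per_family)) {
        father <- if (is.null(pool)) sprintf("%s_O%02d_D", fam, o)
                  else sample(pool, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = sprintf("%s_O%02d", fam, o),
          family_id = fam, provenance_id = prov,
          mother_id = mother, father_id = father,
          stringsAsFactors = FALSE)
      }
    }
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}

# Deterministic random gene templates (one per gene); shared by
# simulate_genotypes (reference alleles) and embed_snps_in_genes.
gene_templates <- function(config) {
  set.seed(config$seed + 4L)
  ids <- sprintf("gene%03d", seq_len(config$n_genes))
  setNames(lapply(ids, function(g)
    sample(c("A", "C", "G", "T"), config$gene_length_bp, replace = TRUE)),
    ids)
}

#' Simulate half-sib genotypes with ground truth
#'
#' Founder allele frequencies are drawn per locus from
#' `Uniform(maf_min, 0.5)`; mother and father genotypes are drawn from
#' Hardy-Weinberg proportions at those frequencies, and each offspring
#' genotype is the sum of one Mendelian maternal gamete and one Mendelian
#' paternal gamete.  Loci are unlinked and placed at distinct random
#' positions in the gene templates.
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param config the same [sim_config()].
#' @param freqs optional numeric vector of length `n_snps` overriding the
#'   drawn founder allele frequencies (values in `[0, 1]`).
#' @return an object of class `capkin_sim`: a list with
#'   \describe{
#'     \item{genotypes}{integer matrix, individuals x loci, alternate-allele
#'       counts in `{0, 1, 2}`.}
#'     \item{freqs}{true founder alternate-allele frequencies per locus.}
#'     \item{loci}{`data.frame` with `locus_id`, `gene_id`, `pos` (1-based
#'       within gene), `ref`, `alt`, `p_true`.}
#'     \item{pedigree}{the input pedigree.}
#'     \item{maternal_gamete, paternal_gamete}{0/1 gamete matrices
#'       (ground truth for Mendelian checks).}
#'   }
#' @export
simulate_genotypes <- function(pedigree, config, freqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_ind <- nrow(pedigree)
  L <- config$n_snps

  # locus placement: distinct (gene, pos) cells, then reference/alternate
  capacity <- config$n_genes * config$gene_length_bp
  if (L > capacity)
    stop("n_snps (", L, ") exceeds assignable positions (", capacity, ")")
  set.seed(config$seed + 3L)
  cell <- sort(sample.int(capacity, L))
  gene_idx <- (cell - 1L) %/% config$gene_length_bp + 1L
  pos <- (cell - 1L) %% config$gene_length_bp + 1L
  templates <- gene_templates(config)
  gene_id <- names(templates)[gene_idx]
  ref <- mapply(function(g, i) templates[[g]][i], gene_id, pos,
                USE.NAMES = FALSE)
  set.seed(config$seed + 3L + 7L)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "", USE.NAMES = FALSE)

  set.seed(config$seed + 2L)
  p <- if (is.null(freqs)) runif(L, config$maf_min, 0.5) else {
    stopifnot(length(freqs) == L, all(freqs >= 0 & freqs <= 1))
    as.numeric(freqs)
  }

  fams <- unique(pedigree$family_id)
  mother_geno <- matrix(rbinom(length(fams) * L, 2L, rep(p, each = length(fams))),
                        nrow = length(fams), dimnames = list(fams, NULL))
  dads <- unique(pedigree$father_id)
  father_geno <- matrix(rbinom(length(dads) * L, 2L, rep(p, each = length(dads))),
                        nrow = length(dads), dimnames = list(dads, NULL))

  # Mendelian gamete from a diploid genotype: 0 -> 0, 2 -> 1, 1 -> coin flip
  gamete <- function(g) {
    out <- as.integer(g == 2L)
    het <- which(g == 1L)
    out[het] <- rbinom(length(het), 1L, 0.5)
    out
  }
  gm <- t(vapply(seq_len(n_ind), function(i)
    gamete(mother_geno[pedigree$family_id[i], ]), integer(L)))
  gp <- t(vapply(seq_len(n_ind), function(i)
    gamete(father_geno[pedigree$father_id[i], ]), integer(L)))
  geno <- gm + gp

  locus_id <- sprintf("%s_%04d", gene_id, pos)
  dimnames(geno) <- list(pedigree$individual_id, locus_id)
  dimnames(gm) <- dimnames(gp) <- dimnames(geno)

  structure(list(
    genotypes = geno,
    freqs = setNames(p, locus_id),
    loci = data.frame(locus_id = locus_id, gene_id = gene_id, pos = pos,
                      ref = ref, alt = alt, p_true = p,
                      stringsAsFactors = FALSE),
    pedigree = pedigree,
    maternal_gamete = gm,
    paternal_gamete = gp
  ), class = "capkin_sim")
}

#' Overlay the observation model on true genotypes
#'
#' Produces a VCF-level view of the true genotype matrix: per-genotype read
#' depth (negative binomial), genotype errors (flip to a random different
#' code), missingness, Phred-like genotype qualities and per-site mapping
#' qualities.  The ground truth is untouched; it stays in the `capkin_sim`
#' object.
#'
#' GQ is modelled as `round(-10 * log10(max(error_rate, 1e-9)))`, capped at
#' 99 and jittered by +/- 2 units: a simple Phred-type scale sufficient to
#' exercise GQ thresholds.
#'
#' @param sim a `capkin_sim` from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return a [variant_table()] with observed codes, DP, GQ and MapQ.
#' @export
apply_observation_model <- function(sim, config) {
  stopifnot(inherits(sim, "capkin_sim"), inherits(config, "sim_config"))
  geno <- sim$genotypes
  if (anyNA(geno)) stop("true genotype matrix must not contain missing values")
  n <- length(geno)
  set.seed(config$seed + 5L)

  dp <- matrix(rnbinom(n, size = config$depth_dispersion,
                       mu = config$mean_depth),
               nrow = nrow(geno), dimnames = dimnames(geno))

  obs <- geno
  flip <- runif(n) < config$genotype_error_rate
  if (any(flip)) {
    # replace by one of the two other codes, uniformly
    obs[flip] <- vapply(obs[flip], function(g)
      sample(setdiff(0:2, g), 1L), integer(1))
  }

  gq_base <- min(99L, round(-10 * log10(max(config$genotype_error_rate, 1e-9))))
  gq <- matrix(pmax(0L, gq_base + sample(-2:2, n, replace = TRUE)),
               nrow = nrow(geno), dimnames = dimnames(geno))

  miss <- runif(n) < config$missing_rate
  obs[miss] <- NA_integer_

  mapq <- pmin(254L, pmax(0L, round(rnorm(ncol(geno), config$mapq_mean, 2))))

  loci <- sim$loci
  variant_table(
    loci = data.frame(chrom = loci$gene_id, pos = loci$pos,
                      id = loci$locus_id, ref = loci$ref, alt = loci$alt,
                      mapq = as.numeric(mapq), stringsAsFactors = FALSE),
    geno = t(obs), dp = t(dp), gq = t(gq),
    individual_ids = rownames(geno))
}

#' Emit per-individual gene sequences carrying the simulated SNPs
#'
#' Each gene gets one random template; every individual's copy of the gene
#' carries its allele at each SNP position (reference base for code 0,
#' alternate base for code 2, the two-base IUPAC ambiguity code for
#' heterozygotes).  Sequences contain no indels, so each gene's set of
#' sequences is a ready-made multiple sequence alignment — the same shape as
#' one-supercontig-per-individual capture output.
#'
#' @param sim a `capkin_sim` from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return a named list of [gene_alignment()] objects (one per gene, in gene
#'   order), with the true templates attached as attribute `templates`
#'   (named character vector).
#' @export
embed_snps_in_genes <- function(sim, config) {
  stopifnot(inherits(sim, "capkin_sim"), inherits(config, "sim_config"))
  templates <- gene_templates(config)
  inds <- rownames(sim$genotypes)
  loci_by_gene <- split(seq_len(nrow(sim$loci)), sim$loci$gene_id)

  alns <- lapply(names(templates), function(g) {
    tmpl <- templates[[g]]
    idx <- loci_by_gene[[g]]
    seqs <- vapply(inds, function(ind) {
      s <- tmpl
      for (j in idx) {
        code <- sim$genotypes[ind, j]
        s[sim$loci$pos[j]] <- switch(as.character(code),
          "0" = sim$loci$ref[j],
          "2" = sim$loci$alt[j],
          "1" = iupac_code(c(sim$loci$ref[j], sim$loci$alt[j])))
      }
      paste(s, collapse = "")
    }, "")
    gene_alignment(g, seqs)
  })
  names(alns) <- names(templates)
  attr(alns, "templates") <-
    vapply(templates, paste, "", collapse = "")
  alns
}
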