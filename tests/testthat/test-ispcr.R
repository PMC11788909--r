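test_that("primer site matching agrees with a sliding-window hand check", {
  tmpl <- "ACGTACGTAAGGCCTTACGTACGTAAGGCCTT"
  p <- "AAGGCCTT"
  hits <- match_sites(p, tmpl, 0)
  expect_equal(hits$start, c(9L, 25L))       # both occurrences reported
  expect_equal(hits$mismatches, c(0L, 0L))
  expect_equal(hits$end, hits$start + nchar(p) - 1L)

  # one substitution: found at 10% of a 20-mer (floor(2)), not at 0%
  t2 <- paste0(strrep("C", 30), "ACGTACGTACGTACGTACGT", strrep("C", 30))
  p2 <- "ACGTACGTACTTACGTACGT"  # one mismatch vs the planted 20-mer
  expect_equal(nrow(match_sites(p2, t2, 0)), 0L)
  h2 <- match_sites(p2, t2, 10)
  expect_equal(h2$start, 31L)
  expect_equal(h2$mismatches, 1L)

  # IUPAC in the template matches compatible bases without a mismatch
  expect_equal(match_sites("ACGT", "AMGT", 0)$mismatches, 0L)
  expect_equal(nrow(match_sites("ACGT", "AKGT", 0)), 0L)
  expect_error(match_sites("", "ACGT", 0), "empty")
  expect_error(match_sites("ACGT", "AC-GZ", 0), "invalid")
})

test_that("designed pairs amplify their own reference exactly once", {
  cfg <- sim_config(n_provenances = 1, families_per_provenance = 3,
                    n_genes = 12, gene_length_bp = 700, n_snps = 60,
                    seed = 71)
  sim <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  alns <- embed_snps_in_genes(sim, cfg)
  ref <- build_reference(alns)
  snps <- data.frame(gene_id = sim$loci$gene_id, pos = sim$loci$pos,
                     locus_id = sim$loci$locus_id)
  pairs <- design_primers(ref, snps, seed = 5)
  expect_gt(nrow(pairs), 3L)
  cn <- primer_constraints()
  seqs <- setNames(ref$consensus, ref$gene_id)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    # independent validation of every design constraint
    for (primer in c(p$fwd, p$rev)) {
      expect_true(nchar(primer) >= cn$primer_len_min &&
                  nchar(primer) <= cn$primer_len_max)
      gc <- mean(strsplit(primer, "")[[1]] %in% c("G", "C"))
      expect_true(gc >= cn$gc_min && gc <= cn$gc_max)
      expect_true(wallace_tm(primer) >= cn$tm_min &&
                  wallace_tm(primer) <= cn$tm_max)
      expect_lte(max(rle(strsplit(primer, "")[[1]])$lengths),
                 cn$max_homopolymer)
    }
    expect_true(p$product_len >= cn$amplicon_min &&
                p$product_len <= cn$amplicon_max)
    # the target SNP lies strictly between the primer footprints
    s <- sim$loci$pos[sim$loci$locus_id == p$locus_id]
    expect_true(s > p$fwd_start + nchar(p$fwd) - 1 &&
                s < p$rev_end - nchar(p$rev) + 1)
    # no known SNP inside either footprint
    gene_snps <- snps$pos[snps$gene_id == p$gene_id]
    expect_false(any(gene_snps >= p$fwd_start &
                     gene_snps <= p$fwd_start + nchar(p$fwd) - 1))
    expect_false(any(gene_snps >= p$rev_end - nchar(p$rev) + 1 &
                     gene_snps <= p$rev_end))
    # exactly one amplimer of the designed length on its own gene
    amp <- enumerate_amplimers(p, seqs[[p$gene_id]], 0)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$length, p$product_len)
  }
  # selected SNPs on one gene are farther apart than the amplicon cap
  for (g in unique(pairs$gene_id)) {
    pos <- sim$loci$pos[sim$loci$locus_id %in%
                          pairs$locus_id[pairs$gene_id == g]]
    if (length(pos) > 1)
      expect_gte(min(diff(sort(pos))), cn$amplicon_max)
  }
})

test_that("design reports failure reasons for impossible targets", {
  ref <- structure(
    data.frame(gene_id = "g1",
               consensus = paste(rep("ACGT", 100), collapse = ""),
               stringsAsFactors = FALSE),
    class = c("reference_set", "data.frame"))
  snps <- data.frame(gene_id = "g1", pos = 10L, locus_id = "edge")
  out <- design_primers(ref, snps, seed = 1)
  expect_equal(nrow(out), 0L)
  fails <- attr(out, "failures")
  expect_equal(fails$reason, "insufficient flank")
  expect_error(design_primers(ref,
    data.frame(gene_id = "nope", pos = 5L, locus_id = "x"), seed = 1),
    "absent from reference")
})

test_that("amplimer enumeration handles absent sites and duplicated genes", {
  set.seed(91)
  gene <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  fwd <- substr(gene, 21, 40)
  rev <- oracle_revcomp(substr(gene, 141, 160))
  pair <- list(fwd = fwd, rev = rev)
  one <- enumerate_amplimers(pair, gene, 0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$length, 140L)
  expect_equal(one$orientation, "canonical")
  # reverse site deleted -> nothing amplifies
  no_rev <- substr(gene, 1, 120)
  expect_equal(nrow(enumerate_amplimers(pair, no_rev, 0)), 0L)
  # duplicated gene copy -> two amplimers (specificity failure visible)
  dup <- paste0(gene, strrep("T", 50), gene)
  expect_equal(nrow(enumerate_amplimers(pair, dup, 0)), 3L)
  # (two within-copy products plus one long cross-copy product)
  expect_equal(nrow(enumerate_amplimers(pair, dup, 0, max_product_bp = 200L)),
               2L)
})

test_that("summaries track planted deletions and mismatch monotonicity", {
  set.seed(95)
  genes <- setNames(vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""), ""),
    paste0("g", 1:4))
  pairs <- do.call(rbind, lapply(1:4, function(i) {
    g <- genes[[i]]
    data.frame(pair_id = paste0("p", i), gene_id = paste0("g", i),
               locus_id = paste0("s", i),
               fwd = substr(g, 31, 50),
               rev = oracle_revcomp(substr(g, 161, 180)),
               fwd_start = 31L, rev_end = 180L, product_len = 150L,
               stringsAsFactors = FALSE)
  }))
  full <- ispcr_summary(pairs, genes, mismatch_pcts = c(10, 0))
  expect_equal(full$pct_with_amplimer, c(100, 100))
  expect_equal(full$pct_single_amplimer, c(100, 100))
  # delete one pair's target region: 3 of 4 pairs amplify
  genes_del <- genes
  genes_del[["g4"]] <- substr(genes_del[["g4"]], 1, 100)
  del <- ispcr_summary(pairs, genes_del, mismatch_pcts = c(0))
  expect_equal(del$pct_with_amplimer, 75)
  # relaxing 0% -> 10% never decreases either percentage
  both <- ispcr_summary(pairs, genes_del, mismatch_pcts = c(10, 0))
  expect_gte(both$pct_with_amplimer[1], both$pct_with_amplimer[2])
  expect_true(all(both$pct_single_amplimer <= both$pct_with_amplimer))
})

test_that("amplimer sets grow monotonically with the mismatch allowance", {
  for (seed in 1:10) {
    inst <- random_ispcr_instance(seed + 400)
    spans0 <- enumerate_amplimers(inst, inst$template, 0)
    spans10 <- enumerate_amplimers(inst, inst$template, 10)
    key <- function(df) paste(df$fwd_start, df$rev_end)
    expect_true(all(key(spans0) %in% key(spans10)))
  }
})

test_that("reverse-complementing the template mirrors amplimer spans", {
  for (seed in 1:10) {
    inst <- random_ispcr_instance(seed + 500)
    L <- nchar(inst$template)
    fwdspans <- enumerate_amplimers(inst, inst$template, 10)
    rcspans <- enumerate_amplimers(inst, revcomp(inst$template), 10)
    mapped <- data.frame(fwd_start = L - fwdspans$rev_end + 1L,
                         rev_end = L - fwdspans$fwd_start + 1L)
    key <- function(df) sort(paste(df$fwd_start, df$rev_end))
    expect_equal(key(rcspans), key(mapped))
  }
})
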