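test_that("allele frequencies count alternate alleles over non-missing calls", {
  m <- rbind(c(0, 2, 0), c(1, 2, 0), c(2, 1, 1), c(NA, NA, 2), c(NA, 2, NA))
  colnames(m) <- c("a", "b", "c")
  expect_equal(unname(allele_frequencies(m[1:3, ])), c(0.5, 5 / 6, 1 / 6))
  expect_equal(unname(allele_frequencies(rbind(c(2, 0), c(2, 0)))), c(1, 0))
  # one missing genotype: p = 3/8
  expect_equal(unname(allele_frequencies(cbind(c(0, 0, 1, NA, 2)))), 3 / 8)
  bad <- cbind(x = c(NA, NA))
  expect_error(allele_frequencies(bad), "x")
})

test_that("the GRM matches a direct evaluation of the formula", {
  M <- rbind(c(0, 1, 2, 1), c(2, 1, 0, 1), c(1, 1, 1, 0))
  rownames(M) <- c("i1", "i2", "i3")
  g <- vanraden_grm(M, "sample")
  expect_lt(max(abs(g$matrix - oracle_grm(M, allele_frequencies(M)))), 1e-10)
  expect_lt(max(abs(g$matrix - t(g$matrix))), 1e-10)

  # with external frequencies and missing values
  M2 <- rbind(c(0, NA, 2, 1), c(2, 1, 0, NA), c(1, 1, NA, 0),
              c(0, 0, 1, 2))
  rownames(M2) <- paste0("j", 1:4)
  p <- c(0.3, 0.5, 0.2, 0.45)
  g2 <- vanraden_grm(M2, p)
  expect_lt(max(abs(g2$matrix - oracle_grm(M2, p))), 1e-10)

  # monomorphic loci are excluded from numerator and denominator
  M3 <- cbind(M, 0L, 2L)
  g3 <- vanraden_grm(M3, "sample")
  expect_equal(g3$n_loci, 4L)
  expect_equal(g3$matrix, g$matrix)
  expect_error(vanraden_grm(cbind(c(0, 0), c(2, 2)), "sample"),
               "monomorphic")
})

test_that("duplicate individuals share diagonal and off-diagonal values", {
  set.seed(12)
  M <- matrix(rbinom(200, 2, 0.4), nrow = 4)
  M[2, ] <- M[1, ]
  rownames(M) <- paste0("i", 1:4)
  g <- vanraden_grm(M, "sample")
  expect_equal(g$matrix[1, 2], g$matrix[1, 1])
  expect_equal(g$matrix[1, 2], g$matrix[2, 2])
})

test_that("true-frequency GRM centers diagonals at 1 and unrelateds at 0", {
  cfg <- sim_config(n_provenances = 2, families_per_provenance = 5,
                    offspring_per_family = 2, n_genes = 200,
                    gene_length_bp = 500, n_snps = 2000, seed = 9)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_genotypes(ped, cfg)
  g <- vanraden_grm(sim$genotypes, sim$freqs)
  expect_lt(abs(mean(diag(g$matrix)) - 1), 0.05)
  same_fam <- outer(ped$family_id, ped$family_id, "==")
  off <- g$matrix[!same_fam & lower.tri(g$matrix)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("sample frequencies from related individuals deflate relatedness", {
  cfg <- sim_config(n_provenances = 1, families_per_provenance = 4,
                    offspring_per_family = 5, n_genes = 100,
                    gene_length_bp = 600, n_snps = 1000, seed = 19)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_genotypes(ped, cfg)
  within_mean <- function(g) {
    mean(unlist(lapply(split(ped$individual_id, ped$family_id), function(m) {
      s <- g$matrix[m, m]; s[lower.tri(s)]
    })))
  }
  g_true <- vanraden_grm(sim$genotypes, sim$freqs)
  g_sample <- vanraden_grm(sim$genotypes, "sample")
  expect_lt(within_mean(g_sample), within_mean(g_true))
})

test_that("PCA coordinates reconstruct the centered GRM and rank clusters", {
  # block-diagonal GRM of two unrelated duplicate pairs
  G <- matrix(0, 4, 4)
  G[1:2, 1:2] <- 1; G[3:4, 3:4] <- 1
  grm <- structure(list(matrix = G, individual_ids = paste0("i", 1:4),
                        freq_source = "external", n_loci = 10L),
                   class = "grm")
  pca <- grm_pca(grm, 3)
  expect_gt(abs(pca$coordinates[1, 1] - pca$coordinates[3, 1]), 0.5)
  expect_lt(abs(pca$coordinates[1, 1] - pca$coordinates[2, 1]), 1e-8)
  # full-rank reconstruction of the double-centered matrix
  n <- 4
  J <- diag(n) - 1 / n
  Gc <- J %*% G %*% J
  recon <- pca$coordinates %*% t(pca$coordinates)
  expect_lt(max(abs(recon - Gc)), 1e-8)
  expect_error(grm_pca(grm, 4), "n_components")
  # eigenvalues are sorted descending
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
})

test_that("grouping similarity scores nearest-centroid agreement", {
  set.seed(33)
  ped <- data.frame(individual_id = paste0("i", 1:6),
                    family_id = rep(c("f1", "f2"), each = 3))
  coords <- rbind(matrix(c(0, 0), 3, 2, byrow = TRUE) + runif(6, 0, 0.01),
                  matrix(c(10, 10), 3, 2, byrow = TRUE) + runif(6, 0, 0.01))
  rownames(coords) <- ped$individual_id
  expect_equal(grouping_similarity(coords, ped)$similarity, 1.0)
  # one individual sitting on the other family's centroid
  coords2 <- coords
  coords2["i1", ] <- colMeans(coords[4:6, ])
  expect_equal(grouping_similarity(coords2, ped)$similarity, 5 / 6)
  # degenerate geometry warns
  flat <- matrix(1, 6, 2, dimnames = list(ped$individual_id, NULL))
  expect_warning(grouping_similarity(flat, ped), "degenerate")
})

test_that("family summaries aggregate within-family pairs", {
  G <- diag(3)
  G[1, 2] <- G[2, 1] <- 0.2
  G[1, 3] <- G[3, 1] <- 0.3
  G[2, 3] <- G[3, 2] <- 0.4
  grm <- structure(list(matrix = G, individual_ids = paste0("i", 1:3),
                        freq_source = "sample", n_loci = 5L), class = "grm")
  dimnames(grm$matrix) <- list(grm$individual_ids, grm$individual_ids)
  ped <- data.frame(individual_id = paste0("i", 1:3), family_id = "f1")
  fs <- family_mean_relatedness(grm, ped)
  expect_equal(fs$mean_r, 0.3)
  expect_equal(fs$sd_r, sd(c(0.2, 0.3, 0.4)))
  # pair family: SD 0; singleton family: undefined
  ped2 <- data.frame(individual_id = paste0("i", 1:3),
                     family_id = c("a", "a", "b"))
  fs2 <- family_mean_relatedness(grm, ped2)
  expect_equal(fs2$mean_r, c(0.2, NA))
  expect_equal(fs2$sd_r, c(0, NA))
  expect_error(family_mean_relatedness(grm,
    data.frame(individual_id = "ghost", family_id = "x")), "ghost")
})

test_that("panel correlation is scale-free and order-invariant", {
  cfg <- sim_config(n_provenances = 1, families_per_provenance = 4,
                    n_genes = 100, gene_length_bp = 600, n_snps = 1000,
                    seed = 23)
  sim <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  g1 <- vanraden_grm(sim$genotypes[, 1:500], sim$freqs[1:500])
  g2 <- vanraden_grm(sim$genotypes[, 501:1000], sim$freqs[501:1000])
  r <- grm_correlation(g1, g2)
  # direct evaluation on the extracted vectors
  sel <- lower.tri(g1$matrix, diag = TRUE)
  expect_equal(r, cor(g1$matrix[sel], g2$matrix[sel]))
  expect_gt(r, 0.5)
  expect_equal(grm_correlation(g1, g1), 1.0)
  g2_scaled <- g2; g2_scaled$matrix <- 2 * g2$matrix
  expect_equal(grm_correlation(g2, g2_scaled), 1.0)
  # reorder individuals in one GRM: matched by id, result unchanged
  perm <- rev(seq_along(g2$individual_ids))
  g2_perm <- g2
  g2_perm$matrix <- g2$matrix[perm, perm]
  g2_perm$individual_ids <- g2$individual_ids[perm]
  expect_equal(grm_correlation(g1, g2_perm), r)
  g_bad <- g2; g_bad$individual_ids[1] <- "other"
  rownames(g_bad$matrix)[1] <- colnames(g_bad$matrix)[1] <- "other"
  expect_error(grm_correlation(g1, g_bad), "different individual")
})
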