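# Realized genomic relatedness from SNP genotypes.
#
# The genomic relationship matrix follows VanRaden's first method:
# G = (M - P)(M - P)' / (2 * sum_j p_j (1 - p_j)), where M holds genotype
# codes 0/1/2, P has column j equal to 2 p_j, and p_j is the alternate
# allele frequency.  Off-diagonal entries estimate realized additive
# relatedness (expected 0.25 for half-sibs); the diagonal is 1 + F.

#' Per-locus allele frequencies from a genotype matrix
#'
#' @param matrix integer matrix, individuals x loci, codes `0/1/2/NA`.
#' @return numeric vector of alternate-allele frequencies
#'   `p = sum(codes) / (2 * non-missing count)` per locus.
#' @export
allele_frequencies <- function(matrix) {
  stopifnot(is.matrix(matrix))
  n <- colSums(!is.na(matrix))
  if (any(n == 0L))
    stop("all genotypes missing at loci: ",
         paste(colnames(matrix)[n == 0L], collapse = ", "))
  colSums(matrix, na.rm = TRUE) / (2 * n)
}

#' VanRaden genomic relationship matrix
#'
#' Missing codes are imputed to the locus mean (`2 p_j`) before centering,
#' so they contribute nothing to relatedness.  Loci whose allele frequency
#' is 0 or 1 carry no information and are excluded from both the numerator
#' and the denominator.
#'
#' When only related individuals are sampled, sample allele frequencies are
#' themselves shaped by the families, which biases relatedness downwards;
#' pass external (e.g., founder or reference-population) frequencies via
#' `freqs` when available.
#'
#' @param matrix integer matrix, individuals x loci, codes `0/1/2/NA`.
#' @param freqs `"sample"` (estimate from `matrix` via
#'   [allele_frequencies()]) or a numeric vector of per-locus alternate
#'   allele frequencies.
#' @return an object of class `grm`: a list with `matrix` (symmetric
#'   individuals x individuals), `individual_ids`, `freq_source`
#'   (`"sample"` or `"external"`), and `n_loci` (loci actually used).
#' @export
vanraden_grm <- function(matrix, freqs = "sample") {
  stopifnot(is.matrix(matrix))
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(matrix)))
  if (identical(freqs, "sample")) {
    p <- allele_frequencies(matrix)
    src <- "sample"
  } else {
    stopifnot(is.numeric(freqs), length(freqs) == ncol(matrix),
              all(freqs >= 0 & freqs <= 1))
    p <- as.numeric(freqs)
    src <- "external"
  }
  use <- p > 0 & p < 1
  if (!any(use)) stop("all loci monomorphic: GRM denominator is zero")
  M <- matrix[, use, drop = FALSE]
  p <- p[use]
  # mean-impute missing codes, then center by 2p
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (any(miss)) M[miss, j] <- 2 * p[j]
  }
  W <- sweep(M, 2L, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)
  structure(list(matrix = G, individual_ids = ids, freq_source = src,
                 n_loci = sum(use)), class = "grm")
}

#' @exportS3Method print grm
print.grm <- function(x, ...) {
  cat("VanRaden GRM:", length(x$individual_ids), "individuals,",
      x$n_loci, "loci,", x$freq_source, "allele frequencies\n")
  invisible(x)
}

#' Principal component analysis of a GRM
#'
#' Eigendecomposition of the double-centered relationship matrix;
#' coordinates are eigenvectors scaled by the square root of the
#' non-negative eigenvalues, sorted by decreasing eigenvalue (ties broken
#' by original index).  Signs are fixed so that each component's
#' largest-magnitude loading is positive.
#'
#' @param grm a [vanraden_grm()] result.
#' @param n_components number of components (< individual count).
#' @return a list of class `grm_pca`: `coordinates` (individuals x
#'   components), `eigenvalues` (all, descending).
#' @export
grm_pca <- function(grm, n_components = 2L) {
  stopifnot(inherits(grm, "grm"))
  G <- grm$matrix
  if (!all(is.finite(G))) stop("GRM contains non-finite entries")
  n <- nrow(G)
  if (n_components >= n) stop("n_components must be < individual count")
  J <- diag(n) - matrix(1 / n, n, n)
  Gc <- J %*% G %*% J
  Gc <- (Gc + t(Gc)) / 2
  e <- eigen(Gc, symmetric = TRUE)
  ord <- order(-e$values, seq_len(n))
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  k <- seq_len(n_components)
  coords <- vecs[, k, drop = FALSE] %*%
    diag(sqrt(pmax(vals[k], 0)), n_components)
  for (j in k) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(grm$individual_ids, paste0("PC", k))
  structure(list(coordinates = coords, eigenvalues = vals),
            class = "grm_pca")
}

#' Per-family mean pairwise relatedness
#'
#' @param grm a [vanraden_grm()] result covering all pedigree individuals.
#' @param pedigree `data.frame` with `individual_id` and `family_id`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a `data.frame` of class `family_summary`: per family, member
#'   count, number of within-family pairs, mean and SD of the pairwise
#'   relatedness (NA for singleton families).
#' @export
family_mean_relatedness <- function(grm, pedigree, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(grm, "grm"))
  missing_ids <- setdiff(pedigree$individual_id, grm$individual_ids)
  if (length(missing_ids))
    stop("pedigree individuals absent from GRM: ",
         paste(missing_ids, collapse = ", "))
  fams <- unique(pedigree$family_id)
  rows <- lapply(fams, function(f) {
    members <- pedigree$individual_id[pedigree$family_id == f]
    n <- length(members)
    if (n < 2L)
      return(data.frame(family_id = f, n_members = n, n_pairs = 0L,
                        mean_r = NA_real_, sd_r = NA_real_))
    sub <- grm$matrix[members, members, drop = FALSE]
    r <- sub[lower.tri(sub)]
    s <- if (sd_type == "sample") sd(r)
         else sqrt(mean((r - mean(r))^2))
    if (length(r) == 1L && sd_type == "sample") s <- 0
    data.frame(family_id = f, n_members = n, n_pairs = length(r),
               mean_r = mean(r), sd_r = s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("family_summary", "data.frame")
  out
}

#' Agreement between PCA grouping and pedigree grouping
#'
#' Each individual is assigned to the family whose centroid in the top
#' `n_components` PCA coordinates is nearest (Euclidean); the similarity is
#' the fraction of individuals assigned to their own pedigree family.  This
#' is a declared surrogate for visually scored cluster agreement.  Distance
#' ties are broken by family id order; fully degenerate geometry (all
#' coordinates identical) triggers a warning.
#'
#' @param pca a [grm_pca()] result (or a coordinate matrix).
#' @param pedigree `data.frame` with `individual_id` and `family_id`.
#' @param n_components number of leading components to use (default 2).
#' @return a list: `similarity` (fraction in `[0, 1]`), `assigned` (named
#'   character vector of nearest-centroid families).
#' @export
grouping_similarity <- function(pca, pedigree, n_components = 2L) {
  coords <- if (inherits(pca, "grm_pca")) pca$coordinates else pca
  stopifnot(is.matrix(coords))
  n_components <- min(n_components, ncol(coords))
  X <- coords[pedigree$individual_id, seq_len(n_components), drop = FALSE]
  fams <- sort(unique(pedigree$family_id))
  if (length(fams) < 2L) stop("need >= 2 families")
  if (all(apply(X, 2L, function(v) diff(range(v)) == 0)))
    warning("degenerate geometry: all coordinates identical")
  centroids <- t(vapply(fams, function(f) {
    colMeans(X[pedigree$family_id == f, , drop = FALSE])
  }, numeric(n_components)))
  d2 <- outer(rowSums(X^2), rep(1, length(fams))) -
    2 * X %*% t(centroids) +
    outer(rep(1, nrow(X)), rowSums(centroids^2))
  best <- apply(d2, 1L, which.min)      # which.min takes the first tie
  assigned <- setNames(fams[best], pedigree$individual_id)
  list(similarity = mean(assigned == pedigree$family_id),
       assigned = assigned)
}

#' Correlation between two relatedness matrices
#'
#' Pearson correlation of the pairwise relatedness values of two marker
#' panels over the same individuals, computed on the lower triangle with
#' the diagonal (self-relatedness) included by default.
#'
#' @param grm_a,grm_b [vanraden_grm()] results over the same individuals
#'   (matched by id; order may differ).
#' @param include_diagonal include self-relatedness values (default `TRUE`).
#' @return the Pearson correlation coefficient.
#' @export
grm_correlation <- function(grm_a, grm_b, include_diagonal = TRUE) {
  stopifnot(inherits(grm_a, "grm"), inherits(grm_b, "grm"))
  if (!setequal(grm_a$individual_ids, grm_b$individual_ids))
    stop("the two GRMs cover different individual sets")
  ids <- grm_a$individual_ids
  A <- grm_a$matrix[ids, ids]
  B <- grm_b$matrix[ids, ids]
  sel <- lower.tri(A, diag = include_diagonal)
  cor(A[sel], B[sel])
}
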