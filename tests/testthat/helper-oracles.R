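# Independent brute-force oracles.  These deliberately re-derive results
# from first principles (naive loops, no shared code paths with the
# package internals) so they can certify the optimised implementations.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# every ungapped placement of `primer` on the forward strand of `template`
# with at most floor(len * pct / 100) mismatching bases
oracle_match_sites <- function(primer, template, pct) {
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(template, "")[[1]]
  k <- length(p); L <- length(t)
  allow <- floor(k * pct / 100)
  out <- NULL
  for (s in seq_len(max(L - k + 1L, 0L))) {
    mm <- 0L
    for (j in seq_len(k)) {
      tb <- t[s + j - 1L]
      ok <- !is.null(ORACLE_IUPAC[[tb]]) && p[j] %in% ORACLE_IUPAC[[tb]]
      if (!ok) mm <- mm + 1L
    }
    if (mm <= allow) out <- rbind(out, c(start = s, mismatches = mm))
  }
  if (is.null(out)) data.frame(start = integer(), mismatches = integer())
  else as.data.frame(out)
}

# all amplimer spans (fwd_start, rev_end) of a primer pair on a template:
# reverse-strand hits are found as forward-strand occurrences of the
# primer's reverse complement (a different route than the implementation,
# which matches against the reverse-complemented template)
oracle_amplimer_spans <- function(fwd, rev, template, pct,
                                  max_product = 5000L) {
  spans <- NULL
  for (role in 1:2) {
    pf <- if (role == 1) fwd else rev
    pr <- if (role == 1) rev else fwd
    fh <- oracle_match_sites(pf, template, pct)
    rh <- oracle_match_sites(oracle_revcomp(pr), template, pct)
    kf <- nchar(pf); kr <- nchar(pr)
    if (nrow(fh) && nrow(rh)) {
      for (i in seq_len(nrow(fh))) for (j in seq_len(nrow(rh))) {
        f_end <- fh$start[i] + kf - 1L
        r_start <- rh$start[j]
        r_end <- r_start + kr - 1L
        len <- r_end - fh$start[i] + 1L
        if (r_start > f_end && len <= max_product)
          spans <- rbind(spans, c(fh$start[i], r_end))
      }
    }
  }
  if (is.null(spans)) return(matrix(integer(), ncol = 2))
  unique(spans[order(spans[, 1], spans[, 2]), , drop = FALSE])
}

# direct evaluation of G = (M - P)(M - P)' / (2 sum p(1-p)), loops only
oracle_grm <- function(M, p) {
  use <- p > 0 & p < 1
  M <- M[, use, drop = FALSE]; p <- p[use]
  n <- nrow(M); L <- ncol(M)
  denom <- 0
  for (j in seq_len(L)) denom <- denom + 2 * p[j] * (1 - p[j])
  G <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) {
    s <- 0
    for (j in 1:L) {
      xi <- if (is.na(M[i, j])) 2 * p[j] else M[i, j]
      xk <- if (is.na(M[k, j])) 2 * p[j] else M[k, j]
      s <- s + (xi - 2 * p[j]) * (xk - 2 * p[j])
    }
    G[i, k] <- s / denom
  }
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

# random template + primer pair instances for the in-silico PCR oracle
# suite: most pairs are cut from the template (guaranteed sites, with a
# few substitutions injected), some are random (usually no sites)
random_ispcr_instance <- function(seed) {
  set.seed(seed)
  L <- sample(600:2500, 1)
  template <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  kf <- sample(18:24, 1); kr <- sample(18:24, 1)
  if (runif(1) < 0.75) {
    a <- sample(seq_len(L - 400), 1)
    b <- a + sample(120:380, 1)
    fwd <- substr(template, a, a + kf - 1)
    rev <- oracle_revcomp(substr(template, b - kr + 1, b))
    mutate <- function(s, n_sub) {
      ch <- strsplit(s, "")[[1]]
      for (i in sample(seq_along(ch), n_sub))
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      paste(ch, collapse = "")
    }
    if (runif(1) < 0.5) fwd <- mutate(fwd, sample(1:2, 1))
    if (runif(1) < 0.5) rev <- mutate(rev, sample(1:2, 1))
  } else {
    fwd <- paste(sample(c("A", "C", "G", "T"), kf, TRUE), collapse = "")
    rev <- paste(sample(c("A", "C", "G", "T"), kr, TRUE), collapse = "")
  }
  list(fwd = fwd, rev = rev, template = template)
}

# small noisy variant table via the simulator (for filter property suites)
random_variant_table <- function(seed, n_ind_families = 3L, n_snps = 30L) {
  cfg <- sim_config(n_provenances = 1, families_per_provenance = n_ind_families,
                    offspring_per_family = 4, n_genes = 10,
                    gene_length_bp = 300, n_snps = n_snps,
                    genotype_error_rate = 0.01, missing_rate = 0.05,
                    mean_depth = 30, depth_dispersion = 8, seed = seed)
  sim <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  apply_observation_model(sim, cfg)
}
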