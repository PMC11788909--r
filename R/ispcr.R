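# Short-amplicon primer selection and in-silico PCR.
#
# Candidate primer pairs flank identified SNPs on the consensus reference
# under transparent rules (length, GC content, Wallace-rule melting
# temperature, homopolymer cap, SNP-free footprints).  Validation follows
# EMBOSS primersearch semantics: ungapped percent-mismatch matching of
# both primers in both role assignments, enumeration of bounded products
# ("amplimers"), and per-pair specificity summaries.

#' Primer-design constraints
#'
#' @param primer_len_min,primer_len_max primer length bounds, bp (18-24).
#' @param gc_min,gc_max GC-content bounds (fractions, 0.4-0.6).
#' @param amplicon_min,amplicon_max product-size bounds, bp (100-150).
#' @param tm_min,tm_max Wallace-rule melting temperature window, degrees C
#'   (`Tm = 2(A+T) + 4(G+C)`).
#' @param tm_max_diff maximum Tm difference within a pair, degrees C.
#' @param max_homopolymer longest allowed single-base run.
#' @return a list of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_len_min = 18L, primer_len_max = 24L,
                               gc_min = 0.4, gc_max = 0.6,
                               amplicon_min = 100L, amplicon_max = 150L,
                               tm_min = 50, tm_max = 70, tm_max_diff = 5,
                               max_homopolymer = 4L) {
  stopifnot(primer_len_min <= primer_len_max, gc_min <= gc_max,
            amplicon_min <= amplicon_max,
            amplicon_min >= primer_len_min + primer_len_max)
  structure(list(primer_len_min = as.integer(primer_len_min),
                 primer_len_max = as.integer(primer_len_max),
                 gc_min = gc_min, gc_max = gc_max,
                 amplicon_min = as.integer(amplicon_min),
                 amplicon_max = as.integer(amplicon_max),
                 tm_min = tm_min, tm_max = tm_max,
                 tm_max_diff = tm_max_diff,
                 max_homopolymer = as.integer(max_homopolymer)),
            class = "primer_constraints")
}

#' Wallace-rule melting temperature
#' @param primer primer sequence over `{A,C,G,T}`.
#' @return `2(A+T) + 4(G+C)` in degrees C.
#' @export
wallace_tm <- function(primer) {
  s <- .chars(primer)
  gc <- sum(s %in% c("G", "C"))
  2 * (length(s) - gc) + 4 * gc
}

.gc_fraction <- function(s) mean(s %in% c("G", "C"))

.max_run <- function(s) max(rle(s)$lengths)

.primer_ok <- function(s, cn) {
  gc <- .gc_fraction(s)
  if (gc < cn$gc_min || gc > cn$gc_max) return(FALSE)
  tm <- 2 * sum(!(s %in% c("G", "C"))) + 4 * sum(s %in% c("G", "C"))
  if (tm < cn$tm_min || tm > cn$tm_max) return(FALSE)
  if (.max_run(s) > cn$max_homopolymer) return(FALSE)
  all(s %in% c("A", "C", "G", "T"))
}

#' Design primer pairs flanking SNPs
#'
#' SNPs are drawn in random (seeded) order; a SNP is skipped when it lies
#' within `amplicon_max` of an already-selected SNP on the same gene (so
#' one amplicon never carries two selected targets).  For each selected
#' SNP, amplicon placements and primer lengths are scanned in a fixed
#' deterministic order and the first pair satisfying every constraint is
#' kept; footprints must not contain any known SNP position and the target
#' SNP must fall strictly between the primers.
#'
#' @param reference a [build_reference()] result (or named character vector
#'   of gene sequences).
#' @param snps `data.frame` with columns `gene_id`, `pos` (1-based on the
#'   reference sequence), and `locus_id`.
#' @param n_pairs stop after this many designed pairs (`NULL` = all).
#' @param constraints a [primer_constraints()].
#' @param seed integer seed for the SNP selection order.
#' @return a `data.frame` of class `primer_pairs`: `pair_id`, `gene_id`,
#'   `locus_id`, `fwd`, `rev` (both 5'->3'; `rev` is the reverse-strand
#'   primer), `fwd_start`, `rev_end` (1-based on the design reference),
#'   `product_len`.  Per-SNP failures are attached as attribute
#'   `failures` (`locus_id`, `reason`).
#' @export
design_primers <- function(reference, snps, n_pairs = NULL,
                           constraints = primer_constraints(), seed = 1L) {
  seqs <- if (inherits(reference, "reference_set"))
    setNames(reference$consensus, reference$gene_id) else reference
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            all(c("gene_id", "pos", "locus_id") %in% names(snps)))
  off <- setdiff(snps$gene_id, names(seqs))
  if (length(off))
    stop("SNP gene absent from reference: ", paste(unique(off), collapse = ", "))
  cn <- constraints
  snp_pos_by_gene <- split(snps$pos, snps$gene_id)

  set.seed(seed)
  order_idx <- sample.int(nrow(snps))
  selected_pos <- list()
  pairs <- list()
  failures <- list()

  for (i in order_idx) {
    if (!is.null(n_pairs) && length(pairs) >= n_pairs) break
    g <- snps$gene_id[i]
    s <- snps$pos[i]
    near <- selected_pos[[g]]
    if (!is.null(near) && any(abs(near - s) < cn$amplicon_max)) next

    tmpl <- .chars(seqs[[g]])
    glen <- length(tmpl)
    if (s - 1 < cn$primer_len_min + 1 || glen - s < cn$primer_len_min + 1) {
      failures[[length(failures) + 1L]] <-
        data.frame(locus_id = snps$locus_id[i], reason = "insufficient flank")
      next
    }
    all_snps <- snp_pos_by_gene[[g]]
    hit <- NULL
    for (plen in cn$amplicon_min:cn$amplicon_max) {
      a <- s - plen %/% 2L
      if (a < 1L) a <- 1L
      b <- a + plen - 1L
      if (b > glen) { b <- glen; a <- b - plen + 1L }
      if (a < 1L) next
      if (s <= a || s >= b) next
      for (fl in cn$primer_len_min:cn$primer_len_max) {
        fwd_end <- a + fl - 1L
        if (fwd_end >= s) break
        fseq <- tmpl[a:fwd_end]
        if (any(all_snps >= a & all_snps <= fwd_end)) next
        if (!.primer_ok(fseq, cn)) next
        ftm <- 2 * sum(!(fseq %in% c("G", "C"))) + 4 * sum(fseq %in% c("G", "C"))
        for (rl in cn$primer_len_min:cn$primer_len_max) {
          rev_start <- b - rl + 1L
          if (rev_start <= s) break
          rseq <- tmpl[rev_start:b]
          if (any(all_snps >= rev_start & all_snps <= b)) next
          if (!.primer_ok(rseq, cn)) next
          rtm <- 2 * sum(!(rseq %in% c("G", "C"))) + 4 * sum(rseq %in% c("G", "C"))
          if (abs(ftm - rtm) > cn$tm_max_diff) next
          hit <- list(fwd = paste(fseq, collapse = ""),
                      rev = revcomp(paste(rseq, collapse = "")),
                      fwd_start = a, rev_end = b, product_len = plen)
          break
        }
        if (!is.null(hit)) break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      failures[[length(failures) + 1L]] <-
        data.frame(locus_id = snps$locus_id[i],
                   reason = "no pair satisfied constraints")
      next
    }
    selected_pos[[g]] <- c(selected_pos[[g]], s)
    pairs[[length(pairs) + 1L]] <- data.frame(
      pair_id = sprintf("pair%04d", length(pairs) + 1L),
      gene_id = g, locus_id = snps$locus_id[i],
      fwd = hit$fwd, rev = hit$rev,
      fwd_start = hit$fwd_start, rev_end = hit$rev_end,
      product_len = hit$product_len, stringsAsFactors = FALSE)
  }

  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pair_id = character(), gene_id = character(),
               locus_id = character(), fwd = character(), rev = character(),
               fwd_start = integer(), rev_end = integer(),
               product_len = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else
    data.frame(locus_id = character(), reason = character())
  class(out) <- c("primer_pairs", "data.frame")
  out
}

#' Ungapped percent-mismatch primer matching
#'
#' Slides the primer along the forward strand of the template and reports
#' every position where the number of mismatching bases is within
#' `floor(primer_length * max_mismatch_pct / 100)` (EMBOSS primersearch
#' integer behaviour).  IUPAC ambiguity codes in the template match any
#' compatible primer base without counting a mismatch; gaps never match.
#' No indels are considered.
#'
#' @param primer primer sequence, 5'->3', over `{A,C,G,T}`.
#' @param template template sequence (may contain IUPAC codes).
#' @param max_mismatch_pct allowed mismatch percentage (e.g., 0 or 10).
#' @return `data.frame` with `start`, `end` (1-based inclusive) and
#'   `mismatches` for every acceptable placement.
#' @export
match_sites <- function(primer, template, max_mismatch_pct = 0) {
  if (!nzchar(primer) || !nzchar(template)) stop("empty sequence")
  pc <- .chars(primer)
  tc <- .chars(template)
  if (!all(pc %in% c("A", "C", "G", "T")))
    stop("primer must be over {A,C,G,T}")
  bad <- which(!(tc %in% rownames(.COMPAT)))
  if (length(bad))
    stop("invalid template symbol '", tc[bad[1]], "' at position ", bad[1])
  k <- length(pc)
  L <- length(tc)
  empty <- data.frame(start = integer(), end = integer(),
                      mismatches = integer())
  if (k > L) return(empty)
  allow <- floor(k * max_mismatch_pct / 100)
  n_pos <- L - k + 1L
  mm <- integer(n_pos)
  for (j in seq_len(k)) {
    mm <- mm + !.COMPAT[tc[j:(n_pos + j - 1L)], pc[j]]
  }
  start <- which(mm <= allow)
  data.frame(start = start, end = start + k - 1L,
             mismatches = mm[start])
}

#' Enumerate in-silico PCR products of a primer pair on a template
#'
#' An amplimer is produced by a forward-strand hit of one primer and a
#' downstream reverse-strand hit of the other, with product length at most
#' `max_product_bp` and no overlap between the two primer sites.  Both role
#' assignments are tried (forward/reverse and swapped), matching
#' primersearch; amplimers with identical spans are collapsed.
#'
#' @param pair one row of a [design_primers()] result, or any list with
#'   elements `fwd` and `rev`.
#' @param template template sequence string.
#' @param max_mismatch_pct allowed mismatch percentage per primer.
#' @param max_product_bp product length cap (default 5000).
#' @return `data.frame` with `fwd_start`, `rev_end`, `length`,
#'   `fwd_mismatches`, `rev_mismatches`, `orientation` (`"canonical"` or
#'   `"swapped"`), one row per amplimer.
#' @export
enumerate_amplimers <- function(pair, template, max_mismatch_pct = 0,
                                max_product_bp = 5000L) {
  stopifnot(!is.null(pair$fwd), !is.null(pair$rev))
  L <- nchar(template)
  rc <- revcomp(template)
  one_role <- function(p_fwd, p_rev, orientation) {
    fh <- match_sites(p_fwd, template, max_mismatch_pct)
    rh <- match_sites(p_rev, rc, max_mismatch_pct)
    if (!nrow(fh) || !nrow(rh)) return(NULL)
    # map reverse-complement coordinates back to the forward strand
    r_start <- L - rh$end + 1L
    r_end <- L - rh$start + 1L
    combos <- expand.grid(f = seq_len(nrow(fh)), r = seq_len(nrow(rh)))
    f <- combos$f; r <- combos$r
    len <- r_end[r] - fh$start[f] + 1L
    ok <- r_start[r] > fh$end[f] & len <= max_product_bp
    if (!any(ok)) return(NULL)
    data.frame(fwd_start = fh$start[f][ok], rev_end = r_end[r][ok],
               length = len[ok],
               fwd_mismatches = fh$mismatches[f][ok],
               rev_mismatches = rh$mismatches[r][ok],
               orientation = orientation, stringsAsFactors = FALSE)
  }
  out <- rbind(one_role(pair$fwd, pair$rev, "canonical"),
               one_role(pair$rev, pair$fwd, "swapped"))
  if (is.null(out) || !nrow(out))
    return(data.frame(fwd_start = integer(), rev_end = integer(),
                      length = integer(), fwd_mismatches = integer(),
                      rev_mismatches = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  # collapse duplicate spans; canonical orientation and fewer mismatches win
  out <- out[order(out$fwd_start, out$rev_end,
                   out$orientation != "canonical",
                   out$fwd_mismatches + out$rev_mismatches), , drop = FALSE]
  out <- out[!duplicated(out[, c("fwd_start", "rev_end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise in-silico amplification over a template set
#'
#' For each mismatch allowance, counts amplimers per primer pair across all
#' templates and reports the percentage of pairs with at least one amplimer
#' and with exactly one amplimer (specificity: a single-copy target).
#' Running the same pairs against another species' templates measures
#' cross-species transferability.
#'
#' @param pairs a [design_primers()] result (or compatible `data.frame`).
#' @param templates named character vector of template sequences (e.g., a
#'   genome's contigs), or a [build_reference()] result.
#' @param mismatch_pcts mismatch allowances to evaluate (default `c(10, 0)`).
#' @param max_product_bp product length cap.
#' @return a `data.frame` of class `ispcr_summary`: one row per allowance
#'   with `mismatch_pct`, `n_pairs`, `pct_with_amplimer`,
#'   `pct_single_amplimer`; per-pair amplimer counts are attached as
#'   attribute `per_pair` (pairs x allowances matrix).
#' @export
ispcr_summary <- function(pairs, templates, mismatch_pcts = c(10, 0),
                          max_product_bp = 5000L) {
  if (inherits(templates, "reference_set"))
    templates <- setNames(templates$consensus, templates$gene_id)
  stopifnot(nrow(pairs) >= 1L, is.character(templates))
  counts <- matrix(0L, nrow = nrow(pairs), ncol = length(mismatch_pcts),
                   dimnames = list(pairs$pair_id, as.character(mismatch_pcts)))
  for (ci in seq_along(mismatch_pcts)) {
    for (pi in seq_len(nrow(pairs))) {
      n <- 0L
      for (tmpl in templates)
        n <- n + nrow(enumerate_amplimers(pairs[pi, ], tmpl,
                                          mismatch_pcts[ci], max_product_bp))
      counts[pi, ci] <- n
    }
  }
  out <- data.frame(
    mismatch_pct = mismatch_pcts,
    n_pairs = nrow(pairs),
    pct_with_amplimer = 100 * colMeans(counts >= 1L),
    pct_single_amplimer = 100 * colMeans(counts == 1L))
  rownames(out) <- NULL
  attr(out, "per_pair") <- counts
  class(out) <- c("ispcr_summary", "data.frame")
  out
}
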