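# Plurality consensus over per-gene multiple sequence alignments, used to
# assemble a per-species reference from capture data: one consensus per
# gene, concatenated into a reference set for mapping and primer design.

#' A per-gene multiple sequence alignment
#'
#' @param gene_id gene identifier.
#' @param seqs named character vector of aligned sequences (one per
#'   individual) over `{A,C,G,T, IUPAC ambiguity, -, N}`; all the same
#'   length.
#' @return an object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene_id, seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("aligned sequences must carry unique individual ids")
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("aligned sequences must all have the same length (gene ", gene_id, ")")
  structure(list(gene_id = gene_id, seqs = toupper(seqs), length = len),
            class = "gene_alignment")
}

#' @exportS3Method print gene_alignment
print.gene_alignment <- function(x, ...) {
  cat("gene_alignment", x$gene_id, ":", length(x$seqs), "sequences x",
      x$length, "columns\n")
  invisible(x)
}

#' Plurality consensus of one alignment column
#'
#' Ambiguity codes are expanded fractionally across their bases before
#' counting (an `R` contributes 1/2 to A and 1/2 to G).  The most frequent
#' base is returned when its frequency among non-gap symbols reaches
#' `plurality_fraction`; ties among top bases return the IUPAC code of the
#' tied set; a top frequency below the plurality returns the IUPAC code of
#' all observed bases (the consensus never asserts a base the column does
#' not contain); an all-gap column returns `-`.
#'
#' @param column character vector of symbols (one per sequence).
#' @param plurality_fraction required frequency in `(0, 1]` (default 0.5).
#' @return a single consensus symbol.
#' @export
#' @examples
#' column_consensus(c("A", "A", "A", "G", "G"))   # "A"
#' column_consensus(c("A", "A", "G", "G"))        # "R"
column_consensus <- function(column, plurality_fraction = 0.5) {
  stopifnot(length(column) >= 1L,
            plurality_fraction > 0, plurality_fraction <= 1)
  column <- toupper(column)
  w <- c(A = 0, C = 0, G = 0, T = 0)
  n_nongap <- 0
  for (i in seq_along(column)) {
    s <- column[i]
    if (s == "-") next
    b <- .IUPAC[[s]]
    if (is.null(b)) stop("invalid symbol '", s, "' at position ", i)
    w[b] <- w[b] + 1 / length(b)
    n_nongap <- n_nongap + 1
  }
  if (n_nongap == 0) return("-")
  freq <- w / n_nongap
  top <- max(freq)
  if (top < plurality_fraction - 1e-12)
    return(iupac_code(names(freq)[freq > 0]))
  tied <- names(freq)[freq >= top - 1e-12]
  if (length(tied) == 1L) tied else iupac_code(tied)
}

#' Consensus sequence of a gene alignment
#'
#' @param alignment a [gene_alignment()].
#' @param plurality_fraction passed to [column_consensus()].
#' @param drop_gap_columns drop columns whose consensus is a gap (default
#'   `TRUE`), yielding an ungapped reference.
#' @return the consensus sequence as a single string.
#' @export
gene_consensus <- function(alignment, plurality_fraction = 0.5,
                           drop_gap_columns = TRUE) {
  stopifnot(inherits(alignment, "gene_alignment"))
  mat <- do.call(rbind, strsplit(alignment$seqs, ""))
  cons <- vapply(seq_len(ncol(mat)), function(j)
    column_consensus(mat[, j], plurality_fraction), "")
  if (drop_gap_columns) cons <- cons[cons != "-"]
  paste(cons, collapse = "")
}

#' Build a reference set from per-gene alignments
#'
#' Applies [gene_consensus()] to every alignment, preserving input gene
#' order; the concatenation of the per-gene consensi is the species
#' reference used for read mapping and primer design.
#'
#' @param alignments list of [gene_alignment()] objects with unique gene ids.
#' @param plurality_fraction,drop_gap_columns passed to [gene_consensus()].
#' @return a `data.frame` of class `reference_set` with columns `gene_id`
#'   and `consensus`, and attribute `report` (genes processed, mean
#'   consensus length).
#' @export
build_reference <- function(alignments, plurality_fraction = 0.5,
                            drop_gap_columns = TRUE) {
  if (length(alignments) == 0L) {
    warning("no alignments supplied; returning an empty reference set")
    out <- data.frame(gene_id = character(), consensus = character(),
                      stringsAsFactors = FALSE)
    attr(out, "report") <- list(n_genes = 0L, mean_length = NA_real_)
    class(out) <- c("reference_set", "data.frame")
    return(out)
  }
  ids <- vapply(alignments, function(a) a$gene_id, "")
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ", ids[duplicated(ids)][1])
  cons <- vapply(alignments, gene_consensus, "",
                 plurality_fraction = plurality_fraction,
                 drop_gap_columns = drop_gap_columns)
  out <- data.frame(gene_id = ids, consensus = unname(cons),
                    stringsAsFactors = FALSE)
  attr(out, "report") <- list(n_genes = length(ids),
                              mean_length = mean(nchar(cons)))
  class(out) <- c("reference_set", "data.frame")
  out
}
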