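# Nucleotide alphabet helpers shared by the consensus, simulation and
# in-silico PCR code.  All sequences are plain upper-case character strings;
# Biostrings is used at the file boundary only.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# set of bases -> single IUPAC symbol ("ACG" -> "V")
.IUPAC_FROM_SET <- local({
  keys <- vapply(.IUPAC, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(.IUPAC), keys)
})

#' Expand an IUPAC symbol to its base set
#' @param symbol single upper-case IUPAC nucleotide symbol.
#' @return character vector of bases in `{A,C,G,T}`.
#' @keywords internal
iupac_bases <- function(symbol) {
  b <- .IUPAC[[symbol]]
  if (is.null(b)) stop("invalid nucleotide symbol: '", symbol, "'")
  b
}

#' IUPAC symbol for a set of bases
#' @param bases character vector drawn from `{A,C,G,T}`.
#' @return one IUPAC symbol covering exactly those bases.
#' @keywords internal
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  sym <- .IUPAC_FROM_SET[[key]]
  if (is.null(sym)) stop("no IUPAC code for base set: ", key)
  sym
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet (and gaps), so it can be applied to both
#' primer sequences and consensus references carrying ambiguity codes.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTR")   # "YACGT"
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# logical compatibility matrix: rows = template symbol (IUPAC), cols = ACGT.
# A template symbol is compatible with a primer base when the base lies in
# the symbol's expansion; gaps match nothing.
.COMPAT <- local({
  syms <- c(names(.IUPAC), "-")
  m <- matrix(FALSE, nrow = length(syms), ncol = 4,
              dimnames = list(syms, c("A", "C", "G", "T")))
  for (s in names(.IUPAC)) m[s, .IUPAC[[s]]] <- TRUE
  m
})

# split a sequence string into an upper-case character vector
.chars <- function(seq) strsplit(toupper(seq), "")[[1]]
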