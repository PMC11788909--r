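# Readers and writers for the formats at the pipeline boundary: VCF 4.2,
# multi-FASTA, pedigree CSV, GRM TSV.  Parsing of standard formats is
# delegated to vcfR and Biostrings; tables are plain TSV with headers.
# Coordinates are 1-based inclusive throughout (VCF convention).

#' Read a VCF into a VariantTable
#'
#' Extracts the fields the pipeline uses: GT (as alternate-allele counts),
#' per-genotype DP and GQ when present, and the per-site MQ INFO field.
#' Genotypes with any missing allele are missing; absent annotations stay
#' absent (`NULL` matrices / `NA` MapQ), never zero.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return a [variant_table()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, "##fileformat=VCF"))
    stop("not a VCF file (missing ##fileformat header): ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  code_one <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  geno <- matrix(vapply(gt, code_one, integer(1)), nrow = nrow(gt),
                 dimnames = dimnames(gt))

  fmt_has <- function(el) any(grepl(paste0("(^|:)", el, "(:|$)"),
                                    v@gt[, "FORMAT"]))
  dp <- if (fmt_has("DP"))
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- if (fmt_has("GQ"))
    suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))

  mq <- tryCatch(
    suppressWarnings(vcfR::extract.info(v, element = "MQ", as.numeric = TRUE)),
    error = function(e) rep(NA_real_, nrow(fix)))
  if (is.null(mq) || length(mq) != nrow(fix)) mq <- rep(NA_real_, nrow(fix))

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_",
                                         fix$POS)[is.na(ids) | ids == "."]
  variant_table(
    loci = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = ids, ref = fix$REF, alt = fix$ALT, mapq = mq,
                      stringsAsFactors = FALSE),
    geno = geno, dp = dp, gq = gq,
    individual_ids = colnames(gt))
}

#' Write a VariantTable as VCF 4.2
#'
#' Emits GT (plus DP and GQ when present) per genotype and MQ per site.
#' Genotype codes are written as unphased biallelic genotypes
#' (`0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`, missing -> `./.`).
#'
#' @param table a [variant_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  fmt <- c("GT", if (!is.null(table$dp)) "DP", if (!is.null(table$gq)) "GQ")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(table$dp))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (!is.null(table$gq))
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$individual_ids), collapse = "\t"))
  gt_str <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  num_or_dot <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                         scientific = FALSE))
  rows <- vapply(seq_len(nrow(table$loci)), function(i) {
    g <- table$geno[i, ]
    cells <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    if (!is.null(table$dp))
      cells <- paste(cells, num_or_dot(table$dp[i, ]), sep = ":")
    if (!is.null(table$gq))
      cells <- paste(cells, num_or_dot(table$gq[i, ]), sep = ":")
    info <- if (is.na(table$loci$mapq[i])) "." else
      paste0("MQ=", format(table$loci$mapq[i], trim = TRUE))
    paste(c(table$loci$chrom[i], table$loci$pos[i], table$loci$id[i],
            table$loci$ref[i], table$loci$alt[i], ".", ".", info,
            paste(fmt, collapse = ":"), cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a pedigree CSV
#'
#' @param path CSV with at least `individual_id` and `family_id` columns
#'   (a `provenance_id` column is kept when present).
#' @return a pedigree `data.frame`.
#' @export
read_pedigree <- function(path) {
  ped <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "family_id")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual_id in pedigree: ",
         ped$individual_id[duplicated(ped$individual_id)][1])
  ped
}

#' Write a pedigree CSV
#' @param pedigree a pedigree `data.frame`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  write.csv(pedigree, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a (multi-)FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate record ids in FASTA: ", ids[duplicated(ids)][1])
  setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Write per-gene alignments to a directory of FASTA files
#' @param alignments list of [gene_alignment()] objects.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_alignments <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in alignments)
    write_fasta(a$seqs, file.path(dir, paste0(a$gene_id, ".fasta")))
  invisible(dir)
}

#' Read a directory of per-gene FASTA alignments
#' @param dir directory containing one `<gene_id>.fasta` per gene.
#' @return named list of [gene_alignment()] objects, sorted by gene id.
#' @export
read_alignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(files)) stop("no .fasta files in ", dir)
  alns <- lapply(files, function(f)
    gene_alignment(sub("\\.fasta$", "", basename(f)), read_fasta(f)))
  setNames(alns, vapply(alns, function(a) a$gene_id, ""))
}

#' Write a GRM as a square TSV
#'
#' Header row and first column carry the individual ids; entries are written
#' with 15 significant digits.
#'
#' @param grm a [vanraden_grm()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  m <- grm$matrix
  df <- data.frame(id = rownames(m),
                   apply(m, 2L, function(x) sprintf("%.15g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square GRM TSV written by [write_grm()]
#' @param path input path.
#' @return a `grm` object (`freq_source = "file"`).
#' @export
read_grm <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m) || !identical(ids, colnames(m)))
    stop("GRM file is not square with matching ids: ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  structure(list(matrix = m, individual_ids = ids, freq_source = "file",
                 n_loci = NA_integer_), class = "grm")
}

# small TSV writer used for all report tables
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
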