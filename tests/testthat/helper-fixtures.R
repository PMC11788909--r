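# Hand-built 10-locus VCF in which each designed locus violates exactly one
# cascade rule (in rule order), leaving two clean survivors.  The expected
# per-rule tally below is a hand count, independent of apply_filters().
#
# 12 diploid individuals; unless stated otherwise a locus uses the "clean"
# genotype pattern (p = 0.25, 4/12 heterozygous), DP = 30, GQ = 90, MQ = 60.
# Site mean depths: nine loci at 30 and L07 at 4 give a global mean of
# (9*30 + 4)/10 = 27.4, hence bounds [13.7, 54.8]: only L07 falls outside.
#
#   L01  indel (REF "AT")                      -> rule 1
#   L02  multiallelic (ALT "C,G")              -> rule 2
#   L03  single het, MAF = 1/24 < 0.05         -> rule 3
#   L04  2/12 missing > 0.1                    -> rule 4
#   L05  two genotypes at GQ 10, masked ->
#        2/12 missing > 0.1                    -> rule 5
#   L06  MQ = 35 <= 40                         -> rule 6
#   L07  DP = 4, site mean 4 < 13.7            -> rule 7
#   L08  clean                                 -> survivor
#   L09  all heterozygous, Ho = 1 > 0.5        -> rule 8 (het_max = 0.5)
#   L10  clean                                 -> survivor

toy_filter_expectations <- list(
  removed = c(indel = 1L, multiallelic = 1L, maf = 1L, missing = 1L,
              gq = 1L, mapq = 1L, depth = 1L, heterozygosity = 1L),
  survivors = c("L08", "L10"),
  global_mean_dp = 27.4)

write_toy_filter_vcf <- function(path) {
  inds <- sprintf("I%02d", 1:12)
  clean <- c("0/0", "0/0", "0/1", "0/1", "0/0", "0/1",
             "0/0", "1/1", "0/0", "0/1", "0/0", "0/0")
  cells <- function(gt, dp = 30, gq = 90) {
    ifelse(gt == "./.", "./.:.:.", paste(gt, dp, gq, sep = ":"))
  }
  row <- function(id, pos, ref, alt, mq, gtcells) {
    paste(c("chr1", pos, id, ref, alt, ".", ".", paste0("MQ=", mq),
            "GT:DP:GQ", gtcells), collapse = "\t")
  }
  l04 <- c("./.", "./.", "0/1", "0/1", "0/0", "0/1",
           "0/0", "0/0", "0/0", "0/1", "0/0", "0/0")
  l05_gq <- c(10, 10, rep(90, 10))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t"),
    row("L01", 100, "AT", "A", 60, cells(clean)),
    row("L02", 200, "A", "C,G", 60,
        cells(c(rep("0/0", 9), "0/1", "1/2", "0/0"))),
    row("L03", 300, "G", "T", 60, cells(c("0/1", rep("0/0", 11)))),
    row("L04", 400, "C", "T", 60, cells(l04)),
    row("L05", 500, "T", "G", 60, cells(clean, gq = l05_gq)),
    row("L06", 600, "A", "G", 35, cells(clean)),
    row("L07", 700, "C", "A", 60, cells(clean, dp = 4)),
    row("L08", 800, "G", "C", 60, cells(clean)),
    row("L09", 900, "T", "C", 60, cells(rep("0/1", 12))),
    row("L10", 1000, "A", "T", 60, cells(clean)))
  writeLines(lines, path)
  invisible(path)
}
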