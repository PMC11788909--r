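Package: capkin
Title: SNP Marker Development and Kinship Validation from Universal
    Target-Capture Loci
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for developing SNP markers from universal target-capture
    loci (e.g., Angiosperms353 supercontigs) and validating them for kinship
    analysis in species without reference genomes. Builds per-species
    reference sequences as plurality consensi of per-gene multiple sequence
    alignments, applies a reproducible SNP filtering cascade
    (indel/multiallelic removal, minor allele frequency, missingness,
    genotype quality, mapping quality, depth bounds, excess heterozygosity),
    estimates realized genomic relatedness with the VanRaden genomic
    relationship matrix, clusters half-sib families by principal component
    analysis, corrects pedigree assignments from relatedness (exclusion and
    reassignment), and screens short-amplicon primer pairs by in-silico PCR
    with percent-mismatch matching. Includes a half-sib family simulator
    (genotypes, gene sequences, and a noisy VCF-level observation layer)
    used to exercise the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
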