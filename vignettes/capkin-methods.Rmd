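---
title: "Methods: from target-capture loci to a validated kinship panel"
author: "capkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from target-capture loci to a validated kinship panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capkin)
```

# Overview

capkin develops SNP markers from universal target-capture loci and
validates them for kinship analysis. The pipeline has five analytical
stages — consensus reference construction, SNP filtering, genomic
relatedness, pedigree correction, and in-silico PCR — plus a half-sib
simulator that provides ground truth for every stage. This vignette
records the models, the parameters that matter, and the design decisions
taken where the problem leaves genuine freedom.

# The half-sib simulator

The simulator emulates the sampling design typical of tree breeding
collections: open-pollinated families nested in provenances. Each family
consists of `offspring_per_family` offspring (default 5, the usual field
sample) of a single mother; each offspring gets its own, unrelated father.
Under this design the expected additive relatedness of two family members
is exactly 0.25 (they share one parent), which anchors all downstream
validation.

Per locus, a founder alternate-allele frequency is drawn from
Uniform(`maf_min`, 0.5) with `maf_min = 0.05`, so that in the noiseless
limit every locus clears the default MAF filter. Mother and father
genotypes are Hardy–Weinberg draws at that frequency; offspring genotypes
are sums of two Mendelian gametes. Loci are unlinked — appropriate for a
few hundred capture genes scattered across a genome and for the GRM, which
treats loci exchangeably.

The observation layer stands in for sequencing, read mapping and variant
calling. Per genotype it draws a read depth from a negative binomial
(`mean_depth = 30`, dispersion `depth_dispersion = 5`, i.e. visibly
overdispersed as real capture depth is), flips the genotype to a random
different code with probability `genotype_error_rate` (default 0.005),
and hides it with probability `missing_rate` (default 0.02). Genotype
quality is a Phred-like map of the error rate,
`round(-10 log10(max(e, 1e-9)))` capped at 99 and jittered by ±2 — not a
calibrated caller model, but enough structure to exercise a `GQ > 16`
threshold meaningfully. Site mapping quality is drawn around
`mapq_mean = 60`. The true genotypes, gametes, founder frequencies and
gene templates are all retained, so tests can compare any observed
quantity against its generating value.

Every individual also receives one sequence per gene: a shared random
template with its alleles substituted at SNP positions, heterozygotes as
two-base IUPAC codes. One sequence per individual per gene matches the
supercontig-per-individual structure of real capture assemblies, and the
absence of indels makes the sequences pre-aligned by construction.

What the simulator does **not** emulate: linkage disequilibrium,
paralogous gene copies (a major real-world cause of excess
heterozygosity), indels and alignment error, batch effects in depth, or
polyploidy. Passing tests therefore demonstrate the correctness of the
algorithms under the stated model, not robustness to those artefacts.

All randomness flows from one integer seed through fixed per-phase
substreams (seed + 1 pedigree, + 2 founders, + 3 locus placement, + 4
templates, + 5 observation), so every artefact is a pure function of the
configuration; the pipeline is byte-reproducible.

An optional `fathers_per_provenance` pool lets fathers be shared within a
provenance, inducing extra between-family relatedness inside provenances —
a pattern real collections show. Its default (`NULL`, unique fathers)
keeps the 0.25 expectation exact; no published value constrains the pool
size, so it is off unless the user sets it.

# Consensus reference

Each gene's reference is a plurality consensus over its alignment
columns. Ambiguity codes are expanded fractionally (an `R` contributes
1/2 to A and 1/2 to G), gaps are excluded from the denominator, and the
most frequent base is accepted when its frequency among non-gap symbols
reaches `plurality_fraction` (default 0.5). Two deliberate choices:

* **Ties emit IUPAC codes** rather than an arbitrary winner — the result
  is deterministic and information-preserving. The same holds
  below-plurality: the consensus emits the ambiguity code of the observed
  bases, so a consensus base set is always a subset of what the column
  contains.
* **Gap-consensus columns are dropped** by default, yielding an ungapped
  reference suitable as a mapping and primer-design template.

Downstream code does *not* assume ambiguity codes are mismatch-neutral in
general; only the in-silico PCR matcher treats a template ambiguity as
compatible with the primer bases it covers (below).

# The filtering cascade

Rules run in a fixed order, and per-rule removal counts are defined with
respect to that order: (1) indels, (2) multiallelic records, (3) MAF,
(4) missingness, (5) GQ, (6) MapQ, (7) depth, (8) excess heterozygosity.

Key interpretation decisions, each exposed as a configuration switch:

* **Depth is a site-level filter.** "Mean of the depth distribution" is
  read as the mean over per-site mean depths, computed on the *input*
  table before any rule fires; bounds are
  `[min_depth_factor, max_depth_factor] × global mean` (defaults ½ and 2).
  A `depth_mode = "genotype"` alternative masks out-of-range genotypes
  instead. Because the bounds are data-derived, refiltering a filtered
  table can in principle shift them; `min_dp` / `max_dp` pin them
  explicitly when exact idempotence matters. In practice capture depth
  distributions sit well inside the bounds and refiltering is a no-op
  (property-tested on simulated tables).
* **GQ masks genotypes, then missingness re-applies**
  (`gq_mode = "mask"`): a failing genotype becomes missing and the site
  survives only if the missingness rule still passes — the practical
  effect of a caller-style `--minGQ` followed by `--max-missing`. A
  site-level alternative (`gq_mode = "site"`) drops any site with a
  failing genotype.
* **Small-sample mode** (intended for species represented by a single
  family of five): allele frequencies from five individuals cannot
  support a MAF cutoff, so only monomorphic loci are removed, and no
  missing genotypes are tolerated.
* **Thresholds are strict** where conventionally quoted that way
  (`GQ > 16`, `MapQ > 40`); the missingness rule keeps a site when its
  missing fraction is `<= max_missing_fraction`, so a threshold of 0
  means "no missing genotypes".
* **Tightened presets** (`filter_preset("maf02_het")`,
  `filter_preset("maf01")`) bundle the MAF-0.2-plus-heterozygosity and
  MAF-0.1 configurations used when relatedness estimates stay noisy; they
  are plain presets, not special code paths.

The excess-heterozygosity ceiling of 0.5 is the analytic maximum of the
Hardy–Weinberg heterozygote frequency 2p(1−p); observed heterozygosity
above it is a classic signature of collapsed paralogs.

# Genomic relatedness

The GRM follows VanRaden's first method with a single global denominator:
`G = (M − P)(M − P)ᵀ / (2 Σ pⱼ(1 − pⱼ))`. Missing codes are mean-imputed
(`2pⱼ`) before centering, so they contribute nothing; loci with
`p ∈ {0, 1}` are excluded from numerator and denominator alike. The
per-locus-scaled VanRaden variant is deliberately out of scope.

Allele frequencies may be estimated from the sample or supplied
externally. When only related individuals are sampled, sample frequencies
absorb family structure and relatedness is underestimated — the worked
example in the README shows within-family means near 0.14 under sample
frequencies versus ≈ 0.25 under true founder frequencies, with the two
GRMs correlated at ≈ 0.998. Relative relatedness survives; absolute
calibration requires reference-population frequencies.

PCA operates on the double-centered GRM itself (not the genotype matrix),
since the clustering being visualized is of relatedness values.
Coordinates are eigenvectors scaled by the square roots of non-negative
eigenvalues; ordering is by decreasing eigenvalue with index as the
tie-break, and each component's sign is fixed so its largest-magnitude
loading is positive — both purely for determinism.

Family-versus-cluster agreement needs a definition, and "95% similarity
with the expected grouping" style statements do not supply one. capkin's
declared surrogate: assign each individual to the family with the nearest
centroid in the top two PCA coordinates (Euclidean; ties broken by family
id order) and report the fraction assigned to their own pedigree family.
Degenerate geometry (all coordinates identical) triggers a warning.

Cross-panel agreement is the Pearson correlation over the lower triangle
*including* the diagonal (self-relatedness) by default, matching how two
marker panels are conventionally compared with a linear fit; Spearman is
not offered because the comparison is explicitly linear. Family summary
SDs use the sample (n−1) definition, configurable to population.

# Pedigree correction

Two moves, in fixed order, both purely functions of (GRM, pedigree,
config):

1. **Exclusion**: an individual leaves the dataset when its maximum
   off-diagonal relatedness to *any* other individual is below
   `unrelated_threshold` (default 0.1).
2. **Reassignment**: for each remaining individual (in id order, one
   pass, no cascading), mean relatedness to each family's other members
   is computed against the original assignments; the individual moves to
   the best family iff that mean is at least `reassign_threshold`
   (default 0.125) and exceeds the own-family mean by at least `margin`
   (default 0.1). Equal means never move anyone.

No published numeric criteria exist for "low relatedness" or
"connections to another family"; the defaults bracket the half-sib
expectation (0.25, half of it, and a separation margin) and are mandatory,
visible parameters rather than buried constants. Validation plants label
swaps (10% of individuals) and unrelated samples (2%) into 20 simulated
families: across 50 seeds, correction must flag every planted unrelated
sample and strictly improve assignment accuracy; with these defaults it
does so in every seed. A corrected pedigree is a fixed point: re-running
the correction produces no further moves.

# In-silico PCR

Primer design replaces thermodynamic modelling with transparent,
deterministic rules: primer length 18–24 bp, GC 40–60%, Wallace melting
temperature `2(A+T) + 4(G+C)` within 50–70 °C and within 5 °C between the
two primers of a pair, homopolymer runs ≤ 4, amplicon 100–150 bp, the
target SNP strictly between the primers, and no known SNP inside either
footprint (a primer sitting on a variable site genotypes unreliably).
SNPs are drawn in seeded random order, with two selected SNPs on a gene
never closer than the amplicon cap; candidate placements are scanned in a
fixed order (amplicon length ascending, SNP centred, primer lengths
ascending) and the first valid pair wins. Per-SNP failures are reported
with reasons.

Matching follows primersearch semantics: ungapped, the allowance is
`floor(primer_length × pct / 100)` mismatches, template IUPAC codes match
any compatible primer base without penalty (consensus references
legitimately carry ambiguity), and gaps never match. An amplimer is a
forward-strand hit of one primer plus a downstream, non-overlapping
reverse-strand hit of the other with product length ≤ `max_product_bp`
(default 5000); both role assignments are tried and duplicate spans are
collapsed. Summaries report, per mismatch allowance (default 10% and 0%),
the percentage of pairs with at least one amplimer and with exactly one —
the latter indicating a single-copy target. Running the same pairs
against another species' templates measures transferability.

The matcher is validated exhaustively against a brute-force oracle (all
site pairs scored naively) on dozens of random primer/template instances
at both allowances, plus monotonicity in the allowance and strand
symmetry under template reverse-complementation.

# Numerical choices and degenerate inputs

* Plurality and consensus tie comparisons use a 1e-12 slack so fractional
  ambiguity weights (thirds, halves) compare exactly.
* GRM symmetry is enforced by averaging `G` with its transpose
  (differences are at floating-point round-off); the worked-example test
  requires agreement with a direct evaluation to 1e-10.
* All-gap columns return `-`; all-missing loci are uncomputable for MAF
  and heterozygosity and error with the locus named; an empty variant
  table errors in `site_mean_depth()`; an all-monomorphic panel errors in
  `vanraden_grm()` (zero denominator); singleton families report `NA`
  relatedness rather than a fabricated number.
* GRM TSVs carry 15 significant digits and round-trip far below any
  tolerance used downstream.

# Validation scale

The simulation-based suites use problem sizes chosen to make the
statistics they check stable: 20 families × 5 offspring with 1000 loci
for the half-sib expectation (200 within-family pairs; the grand mean is
required to sit in 0.25 ± 0.02), 2000 loci for diagonal/unrelated GRM
properties at tolerance 0.05, 1500 loci × 50 seeds for correction
recovery, and 100 random 30-locus tables for filter idempotence and
monotonicity. These sizes are the package's declared validation
conditions and are deliberately far smaller than a real capture panel.

# Known limitations

* The simulator's clean biallelic, unlinked, diploid world excludes the
  failure modes that motivate several filters in real data (paralogs,
  indels, mapping artefacts); the filters are exercised by planted
  violations instead.
* Relatedness estimated with sample allele frequencies from small related
  samples is biased downward by construction; capkin reports it as
  computed and leaves external frequencies to the user.
* The nearest-centroid grouping similarity is one of many defensible
  cluster-agreement metrics; comparisons across software should use the
  same definition.
* Primer design ignores melting thermodynamics, dimers and hairpins; its
  claims are about in-silico amplification and specificity, not wet-lab
  performance.
* Polyploid genotypes and FASTQ-level read simulation are out of scope.
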