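---
title: "Methods: scanning genomes for population-differentiated SNPs"
author: "PopDiffScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning genomes for population-differentiated SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PopDiffScan)
```

# The model and the procedure

PopDiffScan asks where, and how strongly, allele frequencies differ
between human-scale populations, and what kind of genomic real estate the
most differentiated variants occupy. The pipeline is:

1. **Allele counts.** From diploid genotype dosages (0/1/2 alternate
   alleles, `NA` missing) and a sample→population panel, compute per
   population and site the number of called alleles, the alternate-allele
   count and the observed heterozygote count (`alleleCounts()`). Missing
   genotypes are excluded, never imputed: imputation would require a
   model of its own and the estimators below only need the observed
   counts.
2. **Monomorphic filtering.** Sites with no variation carry no
   differentiation signal and make the estimator's denominator zero.
   `filterMonomorphic()` defaults to dropping sites monomorphic across
   *all populations pooled*. The alternative reading — dropping a site as
   soon as *any single* population is monomorphic — is implemented as
   `mode = "any-pop"`, but it would discard fixed differences, which are
   precisely the highest-F_ST sites an outlier scan is designed to find,
   so it is not the default.
3. **Pairwise F_ST.** Every site is scored for every unordered population
   pair with the two-deme Weir–Cockerham variance-components estimator
   θ̂ = a/(a+b+c) (`wcFst()`), computed from diploid sample sizes, sample
   frequencies and observed heterozygosity. It assumes biallelic sites
   and diploid Hardy–Weinberg-ish sampling within populations, and is
   robust to unequal sample sizes. Hudson's closed-form estimator
   (`hudsonFst()`) is carried as an independent cross-check; the test
   suite verifies the two agree within 0.02 on balanced simulated data.
4. **pdSNP calling.** Within each pair, the top `topFraction` (default
   0.01) of per-site scores are flagged as population-differentiated
   (`callPdSnps()`). Thresholds are per pair, not global: each pair has
   its own genome-wide score distribution.
5. **Genic annotation.** SNPs are mapped to promoter / 5'UTR / coding /
   intron / 3'UTR / intergenic from strand-aware gene models
   (`deriveGeneIntervals()`, `assignRegions()`); genes are tallied into
   pdGenes (≥1 pdSNP) and enriched pdGenes (≥3), and analogously for the
   potentially-functional subset (`tallyGenes()`).
6. **LD pruning.** The pdSNP set is thinned so that no retained pair
   within a 1 Mb window has dosage r² > 0.8 (`ldPrune()`), and the claim
   is *verified*, not assumed, by an exhaustive audit (`ldAudit()`).
7. **Enrichment.** Region composition contrasts are tested with Fisher's
   exact test (`fisherTest2x2()`, `regionOrBattery()`); gene sets with
   the upper-tail hypergeometric test and BH FDR (`hypergeomEnrich()`),
   optionally chromosome by chromosome (`compareByChromosome()`).
8. **Architecture.** Per-chromosome pd proportions are regressed on
   chromosome length and gene count (`perChromosomeStats()`,
   `architectureReport()`), and pairwise mean-pdSNP-F_ST distances are
   summarised as a UPGMA tree (`buildPopulationTree()`).

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `topFraction` | 0.01 | fraction | outlier definition: top 1% of each pair's score distribution |
| `promoterBp` | 5000 | bp | promoter = 5 kb immediately upstream of the TSS, strand-aware |
| `enrichedMin` | 3 | SNPs | a gene is "enriched" with ≥3 pd (or pf-pd) SNPs |
| `windowBp` | 1e6 | bp | LD pruning window |
| `r2Max` | 0.8 | r² | LD ceiling for retained pairs |
| `alpha` | 0.05 | adjusted p | gene-set significance after BH |
| `monomorphicMode` | "pooled" | — | see step 2 above |

# Numerical and design choices

**Multi-locus F_ST is a ratio of sums.** Any "average F_ST over many
SNPs" in this package is Σa / Σ(a+b+c) (and Σnum/Σden for Hudson), never
the mean of per-site ratios. The per-site ratio has heavy-tailed noise at
low-information sites, and by Jensen's inequality its mean is biased
downward — numerically the bias is large enough (tens of percent of the
true value at modest sample sizes) that the mean-of-ratios would fail to
recover a simulated divergence parameter that the ratio-of-sums recovers
to the third decimal. The test suite's parameter-recovery checks rest on
this convention.

**Negative θ̂ values are retained for ranking.** Sampling noise makes
per-site θ̂ slightly negative at undifferentiated sites. Clamping to zero
would pile a large mass of exact ties at 0 and distort the top-percentile
cut; an optional clamp exists only for reporting, never for ranking.

**Percentile ties.** `callPdSnps()` selects the `ceiling(q·n)` highest
finite scores *plus every score tied with the boundary order statistic*.
This makes the rule deterministic and invariant to input permutation; the
selected fraction can exceed q only through boundary ties.

**Single-label region precedence.** Disjoint region proportions require
one label per SNP even where genes overlap. The precedence is
coding > utr5 > utr3 > promoter > intron, configurable in
`assignRegions()`; remaining ties go to the lexicographically smallest
gene id. Multiple transcripts of one gene are merged by union of like
intervals before assignment, because gene-level tallies key on genes, not
transcripts. The bp-composition background (`regionComposition()`)
resolves overlaps with the same precedence so SNP shares and nucleotide
shares are directly comparable.

**LD r² conventions.** r² is the squared Pearson correlation of unphased
dosages over jointly non-missing samples. A site with zero variance among
the compared samples has no defined correlation; it cannot carry LD
information, so it is treated as r² = 0 for pruning. The pruner is greedy
keep-first in position order; the verifiable contract is the
no-high-LD-pair guarantee, which the audit checks exhaustively. A
`lower-maf` victim strategy is available for users who prefer removing
the rarer variant of a conflicting pair; it satisfies the same guarantee.
The window is a per-SNP sliding horizon in base pairs.

**Fisher's test.** Two-sided p-values use the minimum-likelihood rule
(sum all hypergeometric outcomes with point probability ≤ observed,
within a 1e-7 relative tolerance for floating-point ties). The reported
odds ratio is the sample cross-product ratio, with the Haldane–Anscombe
+0.5 correction applied to all four cells iff any cell is zero — not the
conditional-MLE odds ratio, because cross-product ratios are what region
composition contrasts conventionally report. The exact construction of
each 2×2 contrast (which categories form the rows, whether the background
is another SNP category or the genome's bp composition) is explicit
configuration of `regionOrBattery()`.

**BH adjustment** delegates to `stats::p.adjust(method = "BH")` behind a
stable wrapper; per-chromosome enrichment adjusts within each
chromosome's term battery.

**UPGMA** is implemented directly (average linkage, merge height d/2,
size-weighted distance updates) so that tie-breaking is documented and
deterministic: among tied pairs, the one whose sorted smallest member
labels are lexicographically smallest merges first. The implementation is
cross-checked against an independent average-linkage implementation on
tie-free matrices and against cophenetic round-trips on ultrametric
input. Neighbor-joining is delegated to `ape::nj`.

**Degenerate inputs.** Zero requested SNPs yields empty-but-valid
objects; a population with no called alleles at a site makes the site
uncallable for pairs involving it; a chromosome with no SNPs reports `NA`
proportions; constant regression responses return slope 0 and R² = 0 by
the SS_tot convention; empty enrichment queries produce empty rows, not
errors.

# What the simulator emulates — and what it does not

`simulateGenotypes()` draws per-population allele frequencies from the
Balding–Nichols Beta distribution around a uniform ancestral frequency
(default range 0.05–0.95, avoiding near-monomorphic draws), then samples
Hardy–Weinberg diploid dosages. Expected pairwise differentiation equals
the chosen F, which is what makes estimator-recovery tests possible.
Structure options: a scalar F, per-chromosome F (to plant
architecture effects), or a two-level hierarchy (groups diverge at
`fstBetween`, populations within groups at `fstWithin`) for tree-recovery
tests. LD is generated blockwise: consecutive SNPs in a block share one
frequency draw and haplotypes are copied site-to-site with probability
0.95, giving adjacent dosage r² around 0.9 — high enough to exercise
pruning. Gene models are placed with exon/intron structure, CDS and UTRs
on both strands; gene sets can carry one planted enriched set.

Deliberately *not* modelled: coalescent genealogies and recombination
maps, mutation-rate heterogeneity, sequencing error, phasing, admixture,
selection. Passing tests therefore demonstrate that the estimators,
rules and bookkeeping are correct under the stated sampling model — not
that real data meet that model. In particular, real LD decay is
continuous rather than blockwise, and real ancestral frequency spectra
are far from uniform.

# Test problem sizes and calibration design

Parameter-recovery checks use 20,000 independent SNPs at 50 diploids per
population (F ∈ {0.05, 0.1, 0.2}, tolerance ±0.02); tree recovery uses
20 replicates of 4 populations × 3,000 SNPs; pruning audits 2,000 SNPs
in blocks of 10 across two 50 Mb chromosomes; Fisher p-values are checked
against exhaustive enumeration for every 2×2 table with total ≤ 40.
These sizes give comfortable statistical margins while keeping the whole
suite fast on a single core.

The null calibration of the hypergeometric engine (fraction of terms
with raw p < 0.05 ≈ 5%) uses a universe of 2,000 genes, queries of 200
and term sizes 20–40. Those sizes were chosen by computing the exact
null rejection rate analytically: hypergeometric p-values are discrete
and conservative, and with small terms or universes P(p < 0.05) can fall
far below 0.05 for purely combinatorial reasons; at the chosen sizes the
exact rate is 0.040–0.042, so the empirical check is meaningful.

# Known limitations

- Only biallelic SNVs are scored; indels, SVs and multi-allelic records
  are skipped on read.
- No haplotype-phase-aware LD (D'), no windowed or haplotype F_ST, and
  no significance test on F_ST itself — the outlier definition is a pure
  percentile rule, so some pdSNPs are expected even with no true
  differentiation.
- The potentially-functional flag is an input table, not a prediction:
  the package does not model TFBS/miRNA/splice functionality.
- Exact concordance with external pruning tools is not guaranteed (victim
  choice differs); the no-high-LD-pair guarantee is the contract.
- Odds ratios from composition contrasts depend on the chosen 2×2
  construction; the battery makes that construction explicit rather than
  inferring one true table.
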