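---
title: "Detecting uniparental disomy and clonal evolution in F1-hybrid tumor exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting uniparental disomy and clonal evolution in F1-hybrid tumor exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f1loh)
```

## The measurement problem

Tumors arising in first-generation (F1) hybrids of two inbred mouse strains
— here C57Bl/6 × 129Sv/Jae — are heterozygous at every SNP that
distinguishes the parental strains. That design turns loss of
heterozygosity (LOH) into a direct, genome-wide observable: at each
strain-informative SNP the **B-allele frequency** (BAF, the fraction of
reads carrying the 129Sv/Jae allele) is ~0.5 in any diploid heterozygous
cell, and somatic loss of one parental haplotype pushes it toward 0 or 1.
Combining the BAF with the tumor/normal **depth log-ratio**
(logR, a proxy for total copy number) separates three mechanisms that all
look like "high VAF" at a driver locus:

* **copy-neutral LOH / uniparental disomy (UPD)**: one haplotype lost, the
  other duplicated — extreme folded BAF, logR ≈ 0;
* **hemizygous deletion**: one haplotype lost — extreme folded BAF,
  logR ≈ log2(1/2) = −1 in a pure tumor;
* **gain/trisomy**: an extra copy — logR ≈ log2(3/2) ≈ 0.585, folded BAF
  only ≈ 2/3 in a pure tumor, so gains are called from coverage.

This matters biologically because *Kras*-mutant T lineage acute
lymphoblastic leukemias in this system recurrently duplicate the mutant
*Kras* allele through UPD (mutant VAF above 80%), and paired
primary/relapse exomes reveal clonal evolution under MEK/PI3K-inhibitor
selection.

## The mixture model

All expectations come from explicit cell-population counting. A sample is
a mixture of normal cells (fraction $1-p$ for purity $p$) and tumor
subpopulations. At an informative SNP where tumor cells carry $c_{B6}$ and
$c_{129}$ haplotype copies,

$$\mathrm{BAF}_{129} \;=\;
\frac{(1-p)\cdot 1 + p\,c_{129}}{(1-p)\cdot 2 + p\,(c_{B6}+c_{129})} .$$

For a somatic mutation at multiplicity $m$ (copies per mutated cell)
carried by a fraction $f$ of all cells (purity × clone fraction) at a
locus with total copy $c_T$ in carriers and 2 elsewhere,

$$\mathrm{VAF} \;=\; \frac{f\,m}{f\,c_T + (1-f)\cdot 2}.$$

These closed forms are verified in the test suite against an independent
oracle that literally enumerates allele copies over 10,000 integer cells.
Inverting the CN-LOH case gives the purity estimator
$\hat p = 2\,\overline{\mathrm{BAF}}_{\mathrm{folded}} - 1$.

## Calling pipeline and its tunable parameters

1. `compute_baf()` — a site enters the BAF track only if the matched
   normal looks heterozygous (normal BAF in [0.25, 0.75]) **and** both
   samples reach `min_depth = 20` reads. The 20× gate is applied to both
   samples symmetrically — the conservative reading of a depth filter
   defined "between leukemia and control" — and is exposed as a parameter.
2. `compute_logr()` — per-bin log2 tumor/normal depth ratio, centered by
   subtracting the genome-wide median. Centering assumes a
   majority-diploid genome; a massively aneuploid sample would violate it.
3. `segment_track()` — by default one segment per chromosome, matching the
   whole-chromosome scale at which these events occur in this leukemia
   model. An optional recursive binary segmentation (split where the
   folded-BAF mean difference exceeds `split_threshold = 0.15`, keep
   `min_sites = 10` a side, leftmost tie wins) recovers sub-chromosomal
   breakpoints; it is off by default because the default is the method
   actually used for these data.
4. `classify_segment()` — thresholds `baf_loh = 0.85`,
   `logr_neutral = ±0.2`, `logr_del ≤ −0.35`, `logr_gain ≥ +0.3`. No
   canonical numeric cutoffs exist for these calls, so these are this
   package's own operating points: each sits between the purity-1
   expectation (folded BAF → 1, logR → −1 or +0.585) and the null, keeping
   power down to purity ≈ 0.7 at exome depths. Segments with LOH-level BAF
   but logR in no-man's land are reported `RETAINED_HET` with an
   `ambiguous` flag rather than silently forced into a class.
5. `call_mutant_duplication()` — a somatic variant with VAF > 0.8 inside a
   CN_LOH segment is a duplicated mutant allele (UPD); the same VAF inside
   a DELETION segment is explained by hemizygous loss instead. The 0.8 cut
   operationalizes the "above 80%" description and is configurable.

## Primary/relapse clonal dynamics

For each somatic variant the primary and relapse alt/ref counts form a
2×2 table tested with Fisher's exact test (exact at the ~100–150× depths
involved; no asymptotic approximation), with Benjamini–Hochberg adjustment
across the variants of one pair — pairs are independent analyses.
Status rules at `q < alpha = 0.05`: fewer than `lod_reads = 3` alt reads
in the primary (the detection limit of somatic callers at ~100×) makes a
significant relapse variant `DE_NOVO`; the mirror case is `LOST`;
otherwise the VAF direction gives `ENRICHED`/`DEPLETED`; non-significant
variants are `STABLE`. Reported VAFs are rounded half-up to 3 decimals;
internal arithmetic is unrounded.

`detect_heterozygosity_reacquisition()` flags the distinctive reversal in
which a driver duplicated by UPD in the primary returns to heterozygosity
at relapse: the primary call must be a duplication and the
purity-corrected Clopper–Pearson interval of the relapse VAF must overlap
[0.4, 0.6].

`group_clones()` is deliberately a simple average-linkage clustering of
variants in (primary VAF, relapse VAF) space cut at height 0.1 — a
two-sample trajectory grouping, not a phylogeny; clonal-evolution
diagrams of such pairs are schematics, and nothing here pretends to infer
tree structure.

## What the simulator emulates — and what it does not

`simulate_pair()` generates matched normal / primary / relapse read counts
with known truth: per-haplotype copy states from configured CN-LOH,
deletion and gain events per clone; expected BAF/VAF from the mixture
model above; depths Poisson (optionally negative-binomial via
`overdispersion`); alt counts binomial; a symmetric read error rate
(default 0.001) so the normal-het and depth gates see realistic noise.
Informative SNPs are laid out deterministically at `snp_density` per Mb,
so two seeds differ in counts but share identical truth structure. Each
sample consumes its own RNG stream in chromosome order, making runs
byte-reproducible and extensible without perturbing earlier draws.
Coordinates follow VCF convention (1-based) for sites and BED convention
(0-based half-open) for depth bins.

It does **not** emulate: read-level artifacts (mapping bias, strand
bias, GC waves in coverage), indels, subclonal copy-number nesting beyond
the configured clones, or contamination between samples. Passing recovery
tests on these simulations therefore demonstrates that the inference is
correct *given* the counting model, not that real exomes are free of the
artifacts upstream callers must handle.

Default conditions: purity defaults to 0.9; transplanted leukemias are
typically high-purity but the true value is unknown, so recovery tests
sweep {0.7, 0.8, 0.9, 0.95}. The packaged pair configurations use purity
0.98 and clone fractions chosen so that the expected VAF trajectories land
on the two resistance narratives this model system exhibits: a pre-existing resistant
subclone (driver VAF 0.92 → 0.54 with re-acquired heterozygosity, resistance
mutation 0.11 → 0.62) and a de novo resistance mutation (0 → ~0.45 while
the ancestral driver collapses).

## Numerical choices and degenerate inputs

* Fisher p-values use the standard two-sided rule (sum of all outcomes no
  more probable than observed, with the 1 + 1e-7 tie tolerance); the test
  suite checks exact agreement with brute-force hypergeometric enumeration
  for every 2×2 table with total ≤ 60.
* Clopper–Pearson intervals use the beta-quantile closed form; coverage is
  verified by simulation and against `binom.test`.
* Zero-depth bins are excluded from logR (never −Inf); an all-zero normal
  is a fatal input error. VAF at zero depth is an error, not 0.
* Rounding of reported VAFs is half-up (0.5475 → 0.548), matching how
  reported allele frequencies are conventionally quoted, and distinct
  from R's banker's rounding.
* Ties in binary segmentation break to the leftmost candidate; clustering
  input is pre-sorted by variant id — both keep outputs deterministic.

## Problem sizes used in validation

The packaged validation runs use four 50-Mb chromosomes with 50
informative SNPs each for single-event recovery (200 replicates per
condition), the full 19-autosome packaged pair configurations for 100
replicates per resistance narrative, and 200 null pairs of 20 variants
for type-I control. These sizes give binomial standard errors below 2% on
every reported rate while keeping the whole suite comfortably
desk-runnable.

## Known limitations

* Threshold-based classification, not joint purity/ploidy fitting (no
  allele-specific integer copy-number model à la ASCAT); adequate for the
  whole-chromosome, high-purity events this model system produces.
* Median-centered logR cannot see a whole-genome doubling.
* Burden per Mb requires the caller's callable-target size as input; no
  default is baked in because that number is platform-specific.
* Clone grouping ignores copy number when converting VAF to cancer-cell
  fraction; variants inside CN-LOH of only part of their clone would be
  mis-grouped.
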