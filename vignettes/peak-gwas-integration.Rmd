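---
title: "Linking transcription-factor binding regions to GWAS loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking transcription-factor binding regions to GWAS loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakgwas)
```

# The scientific problem

A transcription factor (TF) implicated in a complex disease — the
motivating case is a bHLH factor active in coronary artery smooth
muscle cells and associated with coronary artery disease (CAD) — may
contribute to disease risk by regulating *other* disease loci.
`peakgwas` tests that hypothesis by integrating the TF's ChIP-seq
binding regions with GWAS results through four complementary analyses:

1. **Peak consolidation and target-gene assignment.** Two antibody
   peak sets are intersected into a high-confidence shared set; each
   peak is assigned the single nearest gene whose transcription start
   site (TSS) lies within 50 kb.
2. **Open-chromatin overlap enrichment.** Co-occurrence of two peak
   sets is tested against a background of open-chromatin regions
   (ATAC-seq or DNase hypersensitivity) with a one-sided Fisher exact
   test.
3. **Functional-SNP low-P enrichment.** SNPs with regulatory evidence
   (eQTLs, regulatory-annotation SNPs) that map to TF target genes are
   tested for an excess of small GWAS P-values (P < 0.01), after LD
   pruning, by Fisher and one-sided Kolmogorov–Smirnov tests.
4. **Trait-set enrichment with permutation nulls.** At the gene level,
   TF target genes are tested for over-representation in each trait's
   GWAS candidate genes against the pooled all-GWAS-gene background,
   with a matched-size permutation P-value. At the SNP level, an
   average-max-r² LD statistic between peak SNPs and trait SNPs is
   compared with a trait-label permutation null. A trait passing
   P < 0.05 in both permutation tests is called significant (combined
   cutoff 0.0025).

# Models and statistics

## The 2×2 enrichment table

All Fisher-based analyses reduce to the table
(`k` in-set positives, `n` set size, `K` background positives, `N`
background size), with

* fold enrichment `(k/n)/(K/N)`, computed as `kN/(nK)` so its two
  algebraic forms cannot drift in floating point, and
* a one-sided P-value `P(X >= k)` for
  `X ~ Hypergeometric(N, K, n)`, computed through the exact
  hypergeometric tail so values far below 1e-100 remain meaningful —
  no normal approximation is used anywhere.

```{r}
fold_enrichment(contingency_table(548, 12362, 1488, 81223))
fisher_one_sided(contingency_table(548, 12362, 1488, 81223))
```

## LD pruning

`ld_prune()` scans variants in genomic order and keeps a SNP only if
its r² with every previously kept SNP is at most the threshold
(default 0.3). Two deliberate choices:

* **Boundary.** Sources describing this style of pruning alternate
  between "remove r² > 0.3" and "keep r² < 0.3"; removal here is
  strict (`>`), so a pair at exactly 0.3 is kept.
* **Order.** Which member of a linked pair is dropped is not dictated
  by the statistics; the greedy genomic-order scan is used because it
  is deterministic (no seed) and idempotent.

Pairs absent from the r² table are treated as r² = 0, which matches
how sparse pairwise LD tables are produced in practice.

## One-sided Kolmogorov–Smirnov test

The excess-of-small-P test uses `D+ = sup_x (F_target - F_background)`
with the asymptotic tail `exp(-2 D+² mn/(m+n))`, clipped to [0, 1].
At the sample sizes this pipeline encounters (hundreds to tens of
thousands of SNPs) the asymptotic form is accurate to well below the
reporting precision; an exact small-sample computation would add cost
without changing any decision.

## Matched-size gene-set permutation

For each trait, `n_perms` random gene sets of the trait's size are
drawn uniformly without replacement from the pooled background, each
scored with the same one-sided Fisher test, and

    perm_p = #{ P_random < P_trait } / n_perms .

The strict `<` follows the formula quoted for the gene-level analysis.
Because random sets are size-matched, the mean fold enrichment across
permuted sets is ≈ 1 (the package reports it per trait; the acceptance
checks assert it stays in [0.9, 1.1]). A zero count is displayed as a
floor, e.g. `<1.0e-03` at 1000 permutations.

## Average-max-r² LD statistic and its permutation null

For a trait's SNP set, every peak SNP with at least one recorded r²
against a trait SNP contributes its *maximum* such r²; the statistic
is the mean over contributing peak SNPs. Peak SNPs without a recorded
pair are excluded from the denominator rather than zero-filled — the
alternative would silently conflate "no LD data" with "no LD" and
would break the bookkeeping column that counts trait SNPs having r²
with peak SNPs. Each peak SNP therefore maps to at most one trait
SNP, while one trait SNP may be the best partner of several peak
SNPs.

The null is built by drawing, per permutation, an equal-size SNP set
uniformly without replacement from the pooled catalog SNPs —
equivalent to permuting trait labels restricted to the tested trait;
the quoted description supports either reading and this one is exact
under exchangeability (verified by a calibration test). Here

    perm_p = #{ null average >= true average } / n_perms ,

with `>=` (inclusive), in deliberate contrast to the strict `<` of the
gene-level test: the two conventions are preserved as quoted for each
analysis. Permutations where no drawn SNP has any recorded r² are
dropped from the denominator; if more than half are undefined the
test aborts with a diagnostic rather than report a P-value from a
vacuous null.

Both r² sources (mimicking an array-based CEU panel and a
sequencing-based European panel) are merged before analysis: a pair
present in both takes the arithmetic mean, a pair present in one
keeps its value.

## Two further conventions

* **Peak-to-gene distance** is measured from the peak midpoint to the
  TSS. Midpoint (rather than summit or edge) is the only anchor
  available after intersection, since intersected peaks have no
  summit. Ties break to the smaller TSS, then the smaller gene id,
  for determinism. Strand is ignored; the 50 kb window is symmetric.
* **Peak intersection** emits, per overlapping pair, the contained
  peak under complete overlap (equal intervals give that interval)
  and the overlap segment otherwise; both cases equal the pairwise
  intersection, which is how the rule is implemented. One peak
  overlapping several partners yields one output interval per pair;
  exact duplicates are collapsed.

# The synthetic-data generator

`simulate_study()` produces every input the pipeline consumes, from a
single seed, so all stages are testable offline:

* **Genes and peaks.** TSSs uniform per chromosome; 90% of peaks
  placed within 100 kb of a TSS by default (matching the near-TSS
  concentration seen in TF ChIP-seq), lengths geometric around 500 bp
  (typical of consolidated TF peaks). A second antibody set is a
  perturbed subset of the first so the intersection is non-trivial.
* **Variants and LD.** SNPs fall in hard blocks (default 10 SNPs);
  within-block pairwise r² is drawn from Beta(1, 3) — a low-skewed
  distribution typical of pairwise r² in population panels — and
  between-block r² is absent, which makes pruning behaviour exactly
  predictable in tests. Two r² sources are emitted as jittered copies
  of a common truth to exercise the merge rule. LD is generated at
  the r² summary level, not via haplotypes: the pipeline consumes
  only r² tables, so haplotype simulation would add untested surface.
* **Planted effects.** Three independent dials, all off by default:
  `target_fraction_of_trait` (trait genes drawn from peak targets),
  `low_p_boost` (mixture weight of a Beta(a, 1), a = 0.2, small-P
  component among SNPs mapped to peak target genes;
  `boost_for_fold()` solves the weight needed for a desired fold),
  and `ld_enrichment_r2` (trait SNPs placed in peak-SNP LD blocks
  with their peak-SNP r² redrawn around the requested level).

What the generator does **not** emulate: realistic human LD maps,
allele-frequency spectra, genomic clustering of functional
annotations, or inter-trait genetic correlation. Passing tests
therefore demonstrate the statistical machinery — calibration,
monotonicity, power at planted effects — not concordance with any
real study's counts, which depend on the original sequencing data and
reference panels.

# Problem sizes and numerical choices

The bundled checks use desk-scale study sizes chosen to make each
statistical property measurable:

* Gene-level null calibration uses catalogs with a ~20,000-gene pool
  and 1,500–2,500-gene traits (750 traits total, 300 permutations
  each). The strict-`<` permutation formula is slightly
  anti-conservative under P-value ties, so calibration requires
  tables large enough for the hypergeometric atoms to be small; at
  these sizes the residual bias is under one percentage point.
* SNP-level calibration and power use 20,000-SNP panels in 20-SNP
  blocks with ~500 peaks of ~1 kb (300 traits for calibration, 100
  planted replicates for power). These densities give null draws
  enough recorded r² pairs for the null averages to be stable.
* Fold recovery plants a 2.42-fold low-P excess in 50,000-SNP panels
  across 50 seeds.
* The exact-Fisher sweep enumerates all 635,371 tables with N ≤ 60
  against a direct binomial-coefficient oracle (agreement to 1e-12).

Degenerate inputs are handled explicitly rather than coerced: fold
enrichment with an empty set or empty positives is an error (except
the region-overlap test, which reports fold 0 for an empty overlap
count); an LD pairing with no recorded pairs is an error; a trait
with no SNPs is skipped with a warning; SNPs missing from the GWAS
summary are dropped with a logged count.

# Known limitations

* The permutation-P formulae are the quoted ones; neither adds the
  customary `+1` smoothing, so a P-value of exactly 0 is possible and
  is displayed as a resolution floor (`<1.0e-03`, `<1.0e-04`).
* Whether LD pruning should precede or follow subsetting to a
  category's SNPs is ambiguous in the motivating description; the
  pipeline prunes the full panel once, then subsets, which keeps the
  tested panels nested across categories.
* The region-level unit for open-chromatin overlap enrichment
  (classifying each background region by ≥1 bp overlap with either
  peak set) is the only construction that yields a 2×2 table from the
  stated background; a basepair-level unit would need a different
  null model.
* Real GWAS catalogs carry study-level metadata (ancestry mixtures,
  replication status) far richer than the single ancestry flag
  parsed here.
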