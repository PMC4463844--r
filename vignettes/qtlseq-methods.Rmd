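---
title: "QTL-seq bulked-segregant analysis: models, parameters and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq bulked-segregant analysis: models, parameters and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
library(dplyr)
```

## The method

QTL-seq locates quantitative trait loci by sequencing two pooled DNA
samples ("bulks") drawn from the phenotypic extremes of a segregating
bi-parental population. At every SNP that distinguishes the two parents,
the **SNP-index** of a bulk is the fraction of its reads carrying the
high-parent allele; **Δ(SNP-index)** is the high-bulk index minus the
low-bulk index. Away from any trait locus both bulks are random samples of
the population and Δ fluctuates around 0; at a locus under divergent
selection by the bulking itself, the high bulk is enriched for the
high-parent allele and the low bulk for the low-parent allele, so Δ
approaches +1. Because a single SNP's index is noisy, the genome is scanned
with a sliding window (5 Mb window, 10 kb step by default) and the windowed
mean Δ is compared with confidence bounds simulated under the null
hypothesis of no QTL, conditional on read depth and on the mating design.
Candidate intervals are runs of consecutive significant windows.

The package implements this pipeline end to end — input parsing,
polarization, filtering, indexing, windowing, null simulation, interval
calling, gene overlap — together with the supporting computations a
QTL-seq study leans on (bulk design, marker segregation filtering,
single-marker association, phenotype statistics, nucleotide diversity),
and a synthetic-data generator that reproduces the statistical structure
the analysis assumes.

## Polarization and site filters

Input is a per-site allele-depth table for the two bulks and the two
parents (VCF 4.2 with `AD` fields, or the package's TSV dialect). A site is
kept only when the parents are fixed for opposite alleles — operationally,
each parent places at least 90% of its reads on one allele at parental
depth ≥ 10; both knobs are exposed because real parental resequencing is
itself noisy. The high-parent allele then becomes the counted allele in
both bulks, which makes every downstream statistic invariant to which
parent happens to match the reference assembly (tested on mirrored
inputs). Sites then pass a depth filter (≥ 10 reads in *both* bulks — the
conservative reading of a per-sample minimum) and a call-quality filter
(QUAL ≥ 20). Coordinates are 1-based inclusive throughout; BED export
converts to 0-based half-open at the boundary.

## The null model and its confidence bounds

At a neutral site, each bulk is `k` individuals drawn from the population,
so the per-individual genotype law is fixed by the design: 1:2:1 for an
F2, 7:2:7 for an F4 advanced by single-seed descent (heterozygosity halves
at each of the three selfing rounds), 1:0:1 for RILs. A null replicate
draws `k` genotypes per bulk, forms the bulk allele frequency, draws reads
`Binomial(depth, p(1-ε) + (1-p)ε)`, and records Δ. Empirical two-sided
quantiles at 95% and 99% are tabulated by depth (default 10,000 replicates
per depth; order-statistic quantiles with linear interpolation) and looked
up per SNP at `min(depth_LSB, depth_HSB)`, clamped to the nearest
tabulated depth. A window's bound is the unweighted mean of its SNPs'
bounds — the same averaging used for the window's Δ.

Two numerical points matter here. First, the bulk allele frequency of an
F4 design has mean 1/2 and variance `p(1-p)(1+F)/(2k) = 7/(32k)` with
inbreeding coefficient `F = 3/4`; the test suite checks this against the
exact convolution of the 7:2:7 law. Second, Δ at depth `d` lives on a
lattice of multiples of `1/d`, so empirical-quantile bounds cannot achieve
the nominal exceedance exactly: the achieved rate differs from 5% (or 1%)
by up to the probability mass of the lattice atoms at the bounds (at depth
10 the achieved two-sided 95% exceedance is ≈ 3.5%, i.e. conservative).
Coverage tests therefore compare fresh simulations against the *exactly
enumerated* exceedance at the fitted bounds, and separately verify the
achieved rate is nominal within a discreteness-plus-Monte-Carlo band. No
closed-form CI and no multiple-testing correction across windows are
attempted — the scan is descriptive, as is conventional for this method.

## Interval calling

A window is significant when its Δ lies outside the null bound at the
chosen level and (by default) its mean high-bulk index is ≥ 0.9 and its
mean low-bulk index ≤ 0.1 — the bulk-purity signature of a major locus.
Runs of at least `min_run = 2` consecutive significant windows merge into
an interval whose boundaries are the outermost window endpoints; the
attained level is recorded as 99 when every member window also clears the
99% bound. Physical interval length is the plain difference of the
flanking coordinates (the convention used when intervals are reported by
flanking markers), genetic length the absolute difference of map
positions. Genes overlapping an interval by ≥ 1 bp on either strand are
collected from a GFF3 annotation.

`min_run = 2` is a design choice (the method's sources state no rule): it
suppresses single-window excursions while costing nothing at a 10 kb step,
where adjacent windows share almost all of their SNPs. The index
thresholds can be disabled (`use_index_criteria = FALSE`) to call on the
Δ-confidence machinery alone, and an optional absolute-Δ floor is
available because published scans sometimes quote a fixed Δ cutoff
(ambiguously CI-derived or absolute); it defaults to off.

## The synthetic-data generator

The generator emulates an intra-specific cross between two inbred
landraces differing strongly in 100-seed weight (8.9 g vs 30.1 g), the
population and bulk design of a typical seed-weight QTL-seq study:

* **SNP map** — sites scattered uniformly along chromosomes; each site is
  a fixed parental difference, and which allele matches the reference is
  random, so polarization is exercised in both orientations. The genetic
  scale defaults to 1 cM/Mb, a genome-average figure for a compact legume
  genome (~740 Mb against intraspecific maps of 800–1000 cM); real local
  rates vary by two orders of magnitude, which is one reason desk-scale
  window statistics are noisier than genome-scale ones (below).
* **Breeding** — F1 heterozygous everywhere; three selfing rounds by
  single-seed descent give an F4. Meiosis is Haldane: crossover count per
  chromosome Poisson with mean the genetic length in Morgans, uniform
  breakpoints, no interference. The exact one-locus selfing Markov chain
  (genotype law 7:2:7, heterozygosity 1/8) is the oracle for the breeding
  tests; a two-point check verifies the F2 recombinant fraction equals
  Haldane's `r` and that the F4 conditional contamination is *below* the
  naive three-meiosis bound because selfing homozygosity freezes loci.
* **Phenotypes** — `value = baseline + a(dosage-1) + d[het] + env + noise`
  with `a` defaulting to half the parental difference (10.6 g). The
  environment shifts are drawn once per environment and centred to sum to
  zero, so in a balanced trial an individual's mean equals its genetic
  value in the noise-free limit — making the fully heritable case exact.
  Residual variance is solved from the target entry-mean broad-sense
  heritability `H² = Vg / (Vg + Ve/(e·r))`; genotype-by-environment
  variance is omitted (no analysis surface here requires it). `H²`
  defaults to 0.85, inside the 85–88% range typical of replicated
  seed-weight trials; three environments × two replicates mirror a
  three-year, two-replicate field design.
* **Bulks** — individuals ranked by trial mean; `k = 10` per tail, ties
  broken by id. An optional screen skips heterozygotes at the declared
  causal site, a causal-site-only stand-in for the genome-wide
  marker screen used when real bulks are assembled from confirmed
  homozygous segregants.
* **Reads** — per site and bulk, the true high-allele frequency is
  `(2·n_HH + n_LH)/(2k)`; depth is Poisson(30) truncated at 1; high-allele
  reads are binomial with error rate ε = 0.005 folded toward the other
  allele; the parents are sequenced as fixed-allele samples under the same
  model. Counts conserve depth by construction. No raw reads, alignment or
  base qualities are simulated — counts are the generator's contract.

All stages are deterministic under a fixed seed.

## What the desk-scale simulations do and do not show

The test and acceptance simulations use one 10 Mb chromosome with 2,000
SNPs (and a QTL at 850 kb), so that the whole suite runs in minutes. Two
consequences of this scaling are worth stating plainly.

First, a 5 Mb window on a 10 cM chromosome spans half the genetic map, so
window means mix in substantially more recombinant material than the same
window does at genome scale near a low-recombination QTL. Second, with
`k = 10`, one recombinant haplotype in a bulk moves a window's index by
1/20 = 0.05 over its whole block span, so window means have heavy
bulk-sampling variance that read depth cannot reduce.

Together these set a ceiling on the strict per-window HSB ≥ 0.9 / LSB ≤
0.1 gate under these conditions: across 50 simulations of a major QTL at
`H² = 0.85`, the Δ-confidence machinery alone localizes the causal
position in 50/50 runs, while the full gate calls a covering interval in
42/50 — the misses are all threshold-grazing window means (LSB 0.10–0.15
or HSB 0.86–0.90) at sites whose Δ clears the 99% bound by a wide margin.
The acceptance suite asserts both numbers rather than hiding the second
behind the first: passing the Δ-localization check says the statistical
machinery works; the gate's desk-scale recovery rate says how brittle a
hard index threshold is when the window is wide relative to the map and
the bulks are small. Neither says anything about read-level artifacts of
real data (mapping bias, duplicated regions, segregation-distorted
markers), which the generator deliberately does not model.

## Supporting statistics

* **Segregation filter** — Pearson chi-square of the homozygous classes
  against 1:1 (df 1, no continuity correction); heterozygotes are excluded
  because the informative F4 contrast is between homozygous classes. At
  small counts the asymptotic test is anti-conservative relative to the
  exact binomial test; all decision disagreements for totals ≤ 30 are
  boundary cases (p within 0.02 of α) and always in that direction.
* **Single-marker scan** — regression of the per-individual trial mean on
  high-allele dosage: `R² = 100(1 − RSS₁/RSS₀)`,
  `LOD = (n/2)log₁₀(RSS₀/RSS₁)`, additive effect
  `(mean_HH − mean_LL)/2`. This is the validation surrogate for the
  linkage-map-based interval mapping that dedicated QTL software performs;
  map construction and composite interval mapping are out of scope.
* **Heritability** — method-of-moments variance components from the
  two-way individual × environment ANOVA,
  `H² = Vg/(Vg + Vge/e + Ve/(e·r))`, negative components truncated at
  zero; with one replicate the interaction and error pool.
* **Diversity** — θπ as the average over accession pairs of differences
  per pairwise-compared site (pairwise deletion for missing calls), and
  Watterson's `θw = S/(a₁·L)` with `L` the full region length; both per
  site. Heterozygous calls are masked as missing (a selfing species
  carries few). A SNP is private to a group when polymorphic within it and
  monomorphic in every other group. No selection statistics (e.g.
  Tajima's D) are computed, and no attempt is made to reproduce published
  diversity values from unavailable resequencing panels.

## Degenerate inputs and tie-breaking

Zero-depth sites are a contract violation after filtering and error out of
`snp_index()`. Windows with fewer than `min_snps = 3` SNPs are emitted
flagged with `NA` means rather than dropped, so window coordinates are
stable across runs. Depth lookups off the CI table clamp to the nearest
tabulated depth (ties toward the smaller). Bulk selection breaks phenotype
ties by individual id, making reruns stable. Monomorphic markers carry
`NA` association statistics and a flag; a constant phenotype yields
`R² = LOD = 0`. Transgressive-segregant counting uses a small numeric
tolerance so genetic values exactly at a parental mean are not counted
through floating-point round-off.

## Problem sizes used by the shipped tests

Module tests run on 40–300-site maps with 40–221 individuals; the
acceptance suite uses one 10 Mb chromosome × 2,000 SNPs × 221 individuals
for the scan checks, 50 seeded QTL runs plus 50 null runs for recovery and
specificity, 10,000-replicate null tables, and 20 seeds for parameter
recovery (heritability within ±0.10 of 0.85; causal-marker R² within ±8
points of a generating 40%). These sizes were chosen so the whole suite
exercises every claim at comfortable Monte-Carlo resolution.
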