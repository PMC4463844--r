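# bsaqtl

Tidy R tools for **QTL-seq** — sequencing-based bulked-segregant analysis
(BSA) of bi-parental selfing populations — aimed at plant geneticists
mapping major quantitative trait loci (seed weight, flowering time,
disease resistance) in crops such as chickpea.

In QTL-seq, DNA from the two phenotypic extremes of a segregating
population (e.g. an F4 from two inbred landraces) is pooled into a
low-trait and a high-trait bulk and whole-genome sequenced alongside the
parents. At every parent-differentiating SNP, the **SNP-index** of a bulk
is the fraction of reads carrying the high-parent allele, and

    Δ(SNP-index) = index(high bulk) − index(low bulk)

is ≈ 0 genome-wide under no linkage and → +1 at a causal locus. The
package computes per-SNP and sliding-window (default 5 Mb window, 10 kb
step) indices, attaches confidence bounds simulated under the null
hypothesis of no QTL — conditional on read depth and mating design (F2,
F4 7:2:7, RIL) — and calls candidate intervals as runs of significant
windows (Δ outside the null bound, mean high-bulk index ≥ 0.9, mean
low-bulk index ≤ 0.1), which can be intersected with a GFF3 annotation.

It also ships the supporting computations such a study uses — extreme-bulk
selection, marker 1:1 segregation filtering (chi-square), single-marker
association (R², LOD, additive effect), replicated-trial phenotype
summaries with broad-sense heritability, nucleotide diversity (θπ,
Watterson's θω) with group-private SNP detection — and a full synthetic
data generator: Haldane meiosis, single-seed-descent F4 breeding, a
major-QTL phenotype model with a heritability knob, and Poisson/binomial
read sampling. See `vignettes/qtlseq-methods.Rmd` for the models,
parameter choices and known limitations.

## Worked example

Simulate a 221-individual F4 cross between landraces with 100-seed weights
8.9 g and 30.1 g, a fully penetrant seed-weight QTL at ~850 kb on a 10 Mb
chromosome, 10 + 10 homozygous extreme bulks sequenced at depth ~30, then
scan:

```r
library(bsaqtl)

sim <- simulate_cross(seed = 42, h2 = 1, require_homozygous = TRUE)
sim
#> <bsa_sim> 221 individuals, 2000 sites on 1 chromosome(s)
#>   causal QTL at chr1:856,121 (H2 target 1.00, realized 1.000)

res <- run_qtlseq(sim$counts, c(chr1 = 1e7),
                  design = null_design("F4", k = 10, error_rate = 0.005),
                  seed = 43)
glance(res)
#> # A tibble: 1 × 5
#>   n_sites n_windows n_intervals max_abs_delta level
#> 1    2000      1000           2         0.944  0.95

tidy(res)[, c("chrom", "start", "end", "peak_delta", "peak_pos",
              "hsb_index", "lsb_index", "level_attained")]
#> # A tibble: 2 × 8
#>   chrom   start      end peak_delta peak_pos hsb_index lsb_index level_attained
#> 1 chr1        1 10000000      0.944 2500000.     0.933    0.0575             99
#> 2 chr1  9950001 10000000      0.825 9985000.     0.916    0.0957             99
```

The main called interval covers the causal position: its peak window has
Δ(SNP-index) = 0.944 — far beyond the simulated 99% null bound (≈ 0.60 at
depth 30) — with mean SNP-index 0.93 in the high bulk and 0.06 in the low
bulk, the bulk-purity signature of a major locus. (At this desk scale the
5 Mb window spans half the chromosome's genetic map, so intervals are
broad and a linked terminal fragment is also picked up; see the methods
vignette on scaling.) `autoplot(res)` draws the two index tracks and the
Δ track with its confidence band; `genes_in_interval("genes.gff3", "chr1",
start, end)` lists annotated genes in an interval.

Phenotype and marker utilities work on the same simulated objects:

```r
pheno_summary(sim$pheno)              # per-environment CV, H2, transgressives
single_marker_scan(sim$geno, sim$pheno)  # per-marker R2, LOD, additive effect
segregation_filter(c(rep("LL", 60), rep("HH", 40)))  # chisq = 4, fail at 0.05
```

Real data enter through `read_counts_vcf()` (VCF 4.2 with per-sample `AD`)
or `read_counts_tsv()`; the TSV dialect is a `#`-prefixed header
`chrom pos ref alt qual` followed by `<sample>_ref`/`<sample>_alt` depth
pairs for samples `lsb`, `hsb`, `lp`, `hp`. All coordinates are 1-based
inclusive; BED export is converted at the boundary.

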