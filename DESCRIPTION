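Package: bsaqtl
Title: QTL-Seq Bulked-Segregant Analysis with Simulated Selfing Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for QTL-seq (sequencing-based bulked-segregant
    analysis) of bi-parental selfing populations. Computes per-SNP
    SNP-index and delta(SNP-index) from two-bulk allele-depth data (VCF or
    TSV), scans the genome with sliding windows, attaches simulation-based
    null-hypothesis confidence intervals conditional on read depth and
    mating design, and calls candidate QTL intervals which can be
    intersected with GFF3 gene annotation. Includes a full synthetic-data
    generator (meiosis with Haldane crossovers, single-seed-descent F4
    breeding, major-QTL phenotype model, extreme-tail bulk selection and
    Poisson/binomial read sampling), marker segregation filtering,
    single-marker association (LOD, R-squared, additive effect),
    replicated-trial phenotype summaries with broad-sense heritability,
    and nucleotide-diversity estimators (pairwise theta-pi and Watterson's
    theta-w) with group-private SNP detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    Biostrings,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
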