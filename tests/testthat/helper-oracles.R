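# Independent oracles used across the suite. These deliberately take the
# slow/naive route so they never share code paths with the package.

# exact one-locus selfing Markov chain: genotype probabilities (LL, LH, HH)
# after n_self selfing rounds starting from an F1 heterozygote
selfing_chain_probs <- function(n_self) {
  trans <- matrix(c(1, 0, 0,
                    1 / 4, 1 / 2, 1 / 4,
                    0, 0, 1), 3, 3, byrow = TRUE)
  p <- c(0, 1, 0)
  for (i in seq_len(n_self)) p <- as.vector(p %*% trans)
  stats::setNames(p, c("LL", "LH", "HH"))
}

# brute-force sliding windows: for every window scan ALL records
brute_force_windows <- function(records, chrom_len, window_bp, step_bp,
                                min_snps = 3) {
  starts <- seq(1, chrom_len, by = step_bp)
  do.call(rbind, lapply(starts, function(s) {
    e <- min(s + window_bp - 1, chrom_len)
    inside <- records$pos >= s & records$pos <= e
    n <- sum(inside)
    data.frame(
      start = s, end = e, n_snps = n,
      lsb_index = if (n >= min_snps) mean(records$lsb_index[inside]) else NA,
      hsb_index = if (n >= min_snps) mean(records$hsb_index[inside]) else NA,
      delta = if (n >= min_snps) mean(records$delta[inside]) else NA
    )
  }))
}

# exact null distribution of the bulk high-allele COUNT p = c / (2k):
# k-fold convolution of the per-individual allele-count law {0,1,2}
bulk_allele_count_dist <- function(geno_probs, k) {
  per <- c(geno_probs[["LL"]], geno_probs[["LH"]], geno_probs[["HH"]])
  d <- 1
  for (i in seq_len(k)) {
    nd <- numeric(length(d) + 2)
    for (j in seq_along(d)) nd[j:(j + 2)] <- nd[j:(j + 2)] + d[j] * per
    d <- nd
  }
  d  # probabilities of counts 0 .. 2k
}

# exact null distribution of one bulk's SNP-index at a given depth
exact_index_dist <- function(geno_probs, k, depth, eps = 0) {
  cnt <- bulk_allele_count_dist(geno_probs, k)
  p_vals <- (seq_along(cnt) - 1) / (2 * k)
  out <- numeric(depth + 1)
  for (i in seq_along(cnt)) {
    padj <- p_vals[i] * (1 - eps) + (1 - p_vals[i]) * eps
    out <- out + cnt[i] * stats::dbinom(0:depth, depth, padj)
  }
  out  # probabilities of high-read counts 0 .. depth
}

# exact null distribution of delta(SNP-index) = hsb - lsb
exact_delta_dist <- function(geno_probs, k, depth_lsb, depth_hsb, eps = 0) {
  ph <- exact_index_dist(geno_probs, k, depth_hsb, eps)
  pl <- exact_index_dist(geno_probs, k, depth_lsb, eps)
  vals_h <- (0:depth_hsb) / depth_hsb
  vals_l <- (0:depth_lsb) / depth_lsb
  grid <- outer(vals_h, vals_l, "-")
  pr <- outer(ph, pl)
  agg <- tapply(as.vector(pr), round(as.vector(grid), 12), sum)
  list(values = as.numeric(names(agg)), probs = as.numeric(agg))
}

# exact P(delta outside (lo, hi)) under the enumerated null
exact_outside_prob <- function(dist, lo, hi) {
  sum(dist$probs[dist$values < lo | dist$values > hi])
}

# per-site heterozygosity route to theta-pi (valid with no missing data):
# (1/L) * sum_sites 2 x (n - x) / (n (n - 1))
theta_pi_site_formula <- function(mat) {
  n <- nrow(mat)
  h <- apply(mat, 2, function(col) {
    counts <- table(col)
    x <- counts[1]
    2 * x * (n - x) / (n * (n - 1))
  })
  mean(h)
}

# toy GFF3 writer
write_toy_gff <- function(path, genes) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(genes)), function(i) {
               sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom[i], genes$start[i], genes$end[i],
                       genes$strand[i], genes$id[i])
             }, character(1)))
  writeLines(lines, path)
  path
}

# small simulated experiment shared by several module tests
toy_sim <- function(seed = 1, ...) {
  simulate_cross(n_chrom = 1, chrom_length_bp = 2e6, n_sites_per_chrom = 300,
                 n_individuals = 80, qtl_pos_bp = 5e5, h2 = 1,
                 mean_depth = 30, error_rate = 0, seed = seed, ...)
}
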