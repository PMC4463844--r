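#' Select extreme phenotypic bulks
#'
#' Ranks individuals by their mean trait value across all environments and
#' replicates and assigns the `k` lowest to the low bulk and the `k` highest
#' to the high bulk, emulating the pooling of phenotypically extreme
#' segregants for bulked-segregant sequencing. Ties are broken by individual
#' id (stable). Optionally, heterozygotes at a declared site are skipped
#' while filling each tail — the in-silico analogue of screening bulk
#' candidates for homozygosity before pooling.
#'
#' @param pheno Phenotype tibble ([simulate_phenotypes()] or compatible).
#' @param geno A `geno_matrix` covering the same individuals.
#' @param k Bulk size (default 10 individuals per bulk).
#' @param require_homozygous_at Optional `c(chrom, pos)` (character, numeric
#'   via a length-2 list) or a list `list(chrom=, pos=)`: only individuals
#'   homozygous at that site are eligible.
#' @return A list of class `bulk_sets`: `lsb`, `hsb` (character id vectors),
#'   `k`, and `means` (the ranked per-individual means).
#' @export
select_bulks <- function(pheno, geno, k = 10, require_homozygous_at = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  k <- assert_count(k, "k", min = 1L)
  means <- individual_means(pheno)
  means <- means[means$individual %in% geno$individuals, ]
  if (2 * k > nrow(means)) {
    abort(sprintf("2k = %d exceeds the %d phenotyped individuals.",
                  2L * k, nrow(means)))
  }

  eligible <- rep(TRUE, nrow(means))
  if (!is.null(require_homozygous_at)) {
    rh <- as.list(require_homozygous_at)
    ci <- site_index(geno$map, rh$chrom %||% rh[[1]],
                     as.numeric(rh$pos %||% rh[[2]]))
    dos <- geno$dosage[means$individual, ci]
    eligible <- dos != 1L
  }

  ord <- order(means$mean_value, means$individual)  # stable tie-break on id
  asc <- means$individual[ord]
  ok_asc <- eligible[ord]

  lsb <- asc[ok_asc][seq_len(min(k, sum(ok_asc)))]
  if (length(lsb) < k) {
    abort(sprintf("only %d eligible individuals in the low tail (need k = %d).",
                  length(lsb), k))
  }
  desc <- rev(asc)
  ok_desc <- rev(ok_asc)
  hsb <- desc[ok_desc & !(desc %in% lsb)][seq_len(k)]
  if (anyNA(hsb) || length(hsb) < k) {
    abort(sprintf("fewer than k = %d eligible individuals in the high tail.", k))
  }

  structure(list(lsb = lsb, hsb = hsb, k = k, means = means),
            class = "bulk_sets")
}

#' @export
print.bulk_sets <- function(x, ...) {
  mv <- stats::setNames(x$means$mean_value, x$means$individual)
  cat(sprintf("<bulk_sets> k = %d\n  LSB mean trait: %.2f\n  HSB mean trait: %.2f\n",
              x$k, mean(mv[x$lsb]), mean(mv[x$hsb])))
  invisible(x)
}

#' Sample bulk and parent read counts at every SNP site
#'
#' Generates the allele-depth table that whole-genome sequencing of the two
#' pooled bulks (plus the two parents) would yield. For each site and bulk
#' the true high-allele frequency is `p = (2 nHH + nLH) / 2k`; observed depth
#' is Poisson(`mean_depth`) truncated below at 1; high-allele-supporting
#' reads are Binomial(depth, `p(1-e) + (1-p)e`) with sequencing error rate
#' `e`. Parents are emitted as fixed-allele samples (`p` 0 and 1) under the
#' same read model. High/low alleles are mapped to REF/ALT using the map's
#' per-site reference orientation.
#'
#' @param geno A `geno_matrix`.
#' @param bulks A [select_bulks()] result.
#' @param mean_depth Mean sequencing depth per site and sample (default 30).
#' @param error_rate Per-read error rate toward the other allele, in
#'   `[0, 0.5)` (default 0.005).
#' @param qual_mean Mean of the simulated phred-scaled site quality
#'   (default 60).
#' @param seed Optional integer seed.
#' @return A `count_table` tibble: `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   then `<sample>_ref` / `<sample>_alt` depth pairs for samples
#'   `lsb`, `hsb`, `lp` (low parent), `hp` (high parent).
#' @export
sequence_bulks <- function(geno, bulks, mean_depth = 30, error_rate = 0.005,
                           qual_mean = 60, seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(bulks, "bulk_sets"))
  assert_positive(mean_depth, "mean_depth")
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("`error_rate` must lie in [0, 0.5).")
  }
  if (length(bulks$lsb) == 0L || length(bulks$hsb) == 0L) {
    abort("bulks must be non-empty.")
  }
  with_seed(seed)

  sites <- geno$map$sites
  m <- nrow(sites)
  k2 <- 2 * bulks$k
  p_lsb <- colSums(geno$dosage[bulks$lsb, , drop = FALSE]) / k2
  p_hsb <- colSums(geno$dosage[bulks$hsb, , drop = FALSE]) / k2

  draw <- function(p) {
    d <- pmax(rpois(m, mean_depth), 1L)
    high <- rbinom(m, d, p * (1 - error_rate) + (1 - p) * error_rate)
    list(high = high, low = d - high)
  }
  s_lsb <- draw(p_lsb); s_hsb <- draw(p_hsb)
  s_lp <- draw(rep(0, m)); s_hp <- draw(rep(1, m))

  hi_ref <- sites$high_is_ref
  to_ref_alt <- function(s) {
    list(ref = ifelse(hi_ref, s$high, s$low),
         alt = ifelse(hi_ref, s$low, s$high))
  }
  a <- to_ref_alt(s_lsb); b <- to_ref_alt(s_hsb)
  cp <- to_ref_alt(s_lp); dp <- to_ref_alt(s_hp)

  out <- tibble(
    chrom = sites$chrom, pos = sites$pos,
    ref = ifelse(hi_ref, sites$high_allele, sites$low_allele),
    alt = ifelse(hi_ref, sites$low_allele, sites$high_allele),
    qual = round(pmax(rnorm(m, qual_mean, 5), 1), 1),
    lsb_ref = a$ref, lsb_alt = a$alt,
    hsb_ref = b$ref, hsb_alt = b$alt,
    lp_ref = cp$ref, lp_alt = cp$alt,
    hp_ref = dp$ref, hp_alt = dp$alt
  )
  class(out) <- c("count_table", class(out))
  out
}
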