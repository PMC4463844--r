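#' Build a synthetic catalogue of parent-differentiating SNPs
#'
#' Scatters biallelic SNP sites uniformly along each chromosome. Every site is
#' a fixed difference between the two inbred parents: one allele comes from
#' the low-trait parent, the other from the high-trait parent. Which of the
#' two is the reference-genome base is drawn at random per site, so that
#' downstream polarization to the high-parent allele is exercised in both
#' orientations (the reference genome belongs to neither parent in general).
#'
#' @param n_chrom Number of chromosomes (default 8, a typical diploid legume
#'   karyotype).
#' @param chrom_length_bp Chromosome length in bp; recycled across
#'   chromosomes.
#' @param n_sites_per_chrom Number of SNP sites per chromosome; recycled.
#' @param cM_per_Mb Constant genetic-to-physical scale per chromosome
#'   (centimorgan per megabase); recycled. Default 1, a genome-average rate
#'   for a compact crop genome.
#' @param seed Optional integer seed; identical seeds give identical maps.
#'
#' @return An object of class `snp_map`: a list with
#'   * `chromosomes`: tibble with `chrom`, `length_bp`, `cM_per_Mb`;
#'   * `sites`: tibble with `chrom`, `pos` (1-based, strictly increasing
#'     within chromosome), `low_allele`, `high_allele`, `high_is_ref`.
#' @export
#' @examples
#' m <- make_snp_map(n_chrom = 2, chrom_length_bp = 1e6,
#'                   n_sites_per_chrom = 50, seed = 1)
#' m$chromosomes
make_snp_map <- function(n_chrom = 8, chrom_length_bp = 10e6,
                         n_sites_per_chrom = 1000, cM_per_Mb = 1,
                         seed = NULL) {
  assert_count(n_chrom, "n_chrom", min = 1L)
  assert_positive(chrom_length_bp, "chrom_length_bp")
  if (any(n_sites_per_chrom < 0)) abort("`n_sites_per_chrom` must be >= 0.")
  if (any(cM_per_Mb < 0)) abort("`cM_per_Mb` must be >= 0.")
  with_seed(seed)

  chroms <- tibble(
    chrom = sprintf("chr%d", seq_len(n_chrom)),
    length_bp = as.numeric(rep_len(chrom_length_bp, n_chrom)),
    cM_per_Mb = as.numeric(rep_len(cM_per_Mb, n_chrom))
  )
  n_sites <- rep_len(n_sites_per_chrom, n_chrom)

  bases <- c("A", "C", "G", "T")
  sites <- purrr::map(seq_len(n_chrom), function(i) {
    k <- n_sites[i]
    if (k == 0L) {
      return(tibble(chrom = character(), pos = numeric(),
                    low_allele = character(), high_allele = character(),
                    high_is_ref = logical()))
    }
    pos <- sort(unique(ceiling(runif(k) * chroms$length_bp[i])))
    m <- length(pos)
    low <- sample(bases, m, replace = TRUE)
    # the high-parent allele is any base other than the low-parent one
    high <- vapply(low, function(b) sample(setdiff(bases, b), 1L), character(1))
    tibble(chrom = chroms$chrom[i], pos = pos,
           low_allele = low, high_allele = unname(high),
           high_is_ref = sample(c(TRUE, FALSE), m, replace = TRUE))
  }) |> purrr::list_rbind()

  structure(list(chromosomes = chroms, sites = sites), class = "snp_map")
}

#' @export
print.snp_map <- function(x, ...) {
  cat(sprintf("<snp_map> %d chromosome(s), %d site(s)\n",
              nrow(x$chromosomes), nrow(x$sites)))
  print(x$chromosomes)
  invisible(x)
}

#' @export
format.snp_map <- function(x, ...) {
  sprintf("<snp_map: %d chrom, %d sites>", nrow(x$chromosomes), nrow(x$sites))
}
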