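#' Per-bulk SNP-index
#'
#' The SNP-index of a bulk at a site is the fraction of that bulk's reads
#' carrying the high-parent allele: 0 when every read derives from the
#' low-parent genome, 1 when every read derives from the high-parent genome.
#'
#' @param high_count Reads supporting the high-parent allele (vectorised).
#' @param depth Total reads at the site; must be positive.
#' @return `high_count / depth`, in `[0, 1]`.
#' @export
#' @examples
#' snp_index(7, 10)   # 0.7
snp_index <- function(high_count, depth) {
  if (any(depth <= 0)) {
    abort("`depth` must be positive; zero-depth sites must be filtered out first.")
  }
  if (any(high_count < 0) || any(high_count > depth)) {
    abort("`high_count` must lie in [0, depth].")
  }
  high_count / depth
}

#' Per-SNP SNP-index and delta(SNP-index)
#'
#' Adds both bulks' SNP-indices and their difference
#' `delta = hsb_index - lsb_index` to a polarized site table. With this
#' orientation a locus where the high bulk is fixed for the high-parent
#' allele and the low bulk for the low-parent allele attains `delta = +1`.
#'
#' @param sites A `polarized_sites` tibble ([polarize()], usually after
#'   [filter_sites()]).
#' @return The input with columns `lsb_index`, `hsb_index`, `delta` added.
#' @export
compute_snp_index <- function(sites) {
  out <- dplyr::mutate(
    sites,
    lsb_index = snp_index(.data$lsb_high, .data$lsb_depth),
    hsb_index = snp_index(.data$hsb_high, .data$hsb_depth),
    delta = .data$hsb_index - .data$lsb_index
  )
  class(out) <- unique(c("snp_index_table", class(out)))
  out
}

#' delta(SNP-index) of a record
#'
#' @param record A data frame with `hsb_index` and `lsb_index` columns.
#' @return `hsb_index - lsb_index`, in `[-1, 1]`.
#' @export
delta_snp_index <- function(record) {
  record$hsb_index - record$lsb_index
}

#' Sliding-window averages of SNP-index and delta(SNP-index)
#'
#' Slides a window of `window_bp` (default 5 Mb) along each chromosome in
#' steps of `step_bp` (default 10 kb), starting at position 1; the terminal
#' window is truncated at the chromosome end. Window means are unweighted
#' averages over the SNPs inside (1-based inclusive coordinates); windows
#' holding fewer than `min_snps` SNPs are emitted with `NA` means and
#' flagged `low_snps`.
#'
#' @param records A `snp_index_table`, sorted by (chrom, pos).
#' @param chrom_lengths Named numeric vector (or tibble `chrom`,
#'   `length_bp`) of chromosome lengths.
#' @param window_bp,step_bp Window size and increment in bp; requires
#'   `window_bp >= step_bp > 0`.
#' @param min_snps Minimum SNPs for a reportable window (default 3).
#' @param depth_weighted If `TRUE`, weight each SNP's index by its bulk
#'   depth (ratio-of-sums estimator) instead of the default unweighted mean.
#' @return A `window_stats` tibble: `chrom`, `start`, `end`, `midpoint`,
#'   `n_snps`, `lsb_index`, `hsb_index`, `delta`, `low_snps`.
#' @export
sliding_windows <- function(records, chrom_lengths, window_bp = 5e6,
                            step_bp = 1e4, min_snps = 3,
                            depth_weighted = FALSE) {
  if (step_bp <= 0 || window_bp < step_bp) {
    abort("require `window_bp` >= `step_bp` > 0.")
  }
  lens <- chrom_length_vector(chrom_lengths)

  out <- purrr::imap(lens, function(len, ch) {
    r <- records[records$chrom == ch, ]
    if (is.unsorted(r$pos, strictly = FALSE)) {
      abort(sprintf("records on %s are not sorted by position.", ch))
    }
    starts <- seq(1, len, by = step_bp)
    ends <- pmin(starts + window_bp - 1, len)
    ri <- range_indices(r$pos, starts, ends)
    n <- ri$n
    if (depth_weighted) {
      lsb <- windowed_sum(r$lsb_high, ri$lo, ri$hi, n) /
        windowed_sum(r$lsb_depth, ri$lo, ri$hi, n)
      hsb <- windowed_sum(r$hsb_high, ri$lo, ri$hi, n) /
        windowed_sum(r$hsb_depth, ri$lo, ri$hi, n)
      delta <- hsb - lsb
    } else {
      lsb <- windowed_mean(r$lsb_index, ri$lo, ri$hi, n)
      hsb <- windowed_mean(r$hsb_index, ri$lo, ri$hi, n)
      delta <- windowed_mean(r$delta, ri$lo, ri$hi, n)
    }
    low <- n < min_snps
    tibble(chrom = ch, start = starts, end = ends,
           midpoint = (starts + ends) / 2, n_snps = n,
           lsb_index = ifelse(low, NA_real_, lsb),
           hsb_index = ifelse(low, NA_real_, hsb),
           delta = ifelse(low, NA_real_, delta),
           low_snps = low)
  }) |> purrr::list_rbind()

  class(out) <- unique(c("window_stats", class(out)))
  out
}
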