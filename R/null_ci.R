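#' Describe the no-QTL null design of a bulked-segregant experiment
#'
#' At a neutral (unlinked) site the two bulks are random draws of `k`
#' individuals from the segregating population, so the per-individual
#' genotype law is fixed by the mating design: 1/4 : 1/2 : 1/4 for an F2,
#' 7/16 : 1/8 : 7/16 for an F4 bred by single-seed descent (heterozygosity
#' halves each selfing round), and 1/2 : 0 : 1/2 for fully inbred RILs.
#'
#' @param generation `"F4"` (default), `"F2"` or `"RIL"`.
#' @param k Bulk size (individuals per bulk, default 10).
#' @param error_rate Sequencing error rate toward the other allele.
#' @return A list of class `null_design` with `generation`, `k`,
#'   `geno_probs` (named LL/LH/HH, summing to 1) and `error_rate`.
#' @export
null_design <- function(generation = c("F4", "F2", "RIL"), k = 10,
                        error_rate = 0) {
  generation <- match.arg(generation)
  k <- assert_count(k, "k", min = 1L)
  probs <- switch(generation,
                  F2 = c(LL = 1 / 4, LH = 1 / 2, HH = 1 / 4),
                  F4 = c(LL = 7 / 16, LH = 1 / 8, HH = 7 / 16),
                  RIL = c(LL = 1 / 2, LH = 0, HH = 1 / 2))
  structure(list(generation = generation, k = k, geno_probs = probs,
                 error_rate = error_rate),
            class = "null_design")
}

# k-individual bulk allele frequencies for n_reps replicates
.bulk_freqs <- function(design, n_reps) {
  cnt <- stats::rmultinom(n_reps, design$k, design$geno_probs)
  (2 * cnt[3, ] + cnt[2, ]) / (2 * design$k)
}

#' Simulate delta(SNP-index) under the no-QTL null
#'
#' For each replicate and each bulk independently: draw `k` genotypes from
#' the design's neutral law, form the bulk high-allele frequency `p`, draw
#' high-allele reads Binomial(depth, `p(1-e) + (1-p)e`), and return the
#' difference of the two bulk indices.
#'
#' @param design A [null_design()].
#' @param depth_lsb,depth_hsb Read depths of the two bulks (scalars >= 1).
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_reps` null delta(SNP-index) draws.
#' @export
simulate_null_delta <- function(design, depth_lsb, depth_hsb, n_reps,
                                seed = NULL) {
  stopifnot(inherits(design, "null_design"))
  if (depth_lsb < 1 || depth_hsb < 1) abort("depths must be >= 1.")
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  with_seed(seed)
  eps <- design$error_rate
  adj <- function(p) p * (1 - eps) + (1 - p) * eps
  p_l <- .bulk_freqs(design, n_reps)
  p_h <- .bulk_freqs(design, n_reps)
  idx_l <- rbinom(n_reps, depth_lsb, adj(p_l)) / depth_lsb
  idx_h <- rbinom(n_reps, depth_hsb, adj(p_h)) / depth_hsb
  idx_h - idx_l
}

#' Tabulate null confidence bounds of delta(SNP-index) by read depth
#'
#' For each depth, simulates the null delta(SNP-index) distribution (equal
#' depth in both bulks) and records its empirical two-sided quantiles at
#' each confidence level (order-statistic quantiles with linear
#' interpolation). At lookup time, depths not in the table are clamped to
#' the nearest tabulated depth.
#'
#' @param design A [null_design()].
#' @param depths Integer vector of read depths to tabulate.
#' @param levels Two-sided confidence levels (default 0.95 and 0.99).
#' @param n_reps Replicates per depth (default 10000; below 1000 a warning
#'   flags quantile instability).
#' @param seed Optional integer seed.
#' @return A `ci_table` tibble: `depth`, then `lo<level>` / `hi<level>`
#'   bound columns (e.g. `lo95`, `hi95`, `lo99`, `hi99`). Attributes:
#'   `n_reps`, `seed`, `design`.
#' @export
build_ci_table <- function(design, depths = c(10, 20, 30, 50, 100),
                           levels = c(0.95, 0.99), n_reps = 10000,
                           seed = NULL) {
  stopifnot(inherits(design, "null_design"))
  if (length(depths) == 0L) abort("`depths` must be non-empty.")
  if (n_reps < 1000) warn("n_reps < 1000: empirical quantiles may be unstable.")
  with_seed(seed)

  rows <- purrr::map(sort(unique(depths)), function(d) {
    dl <- simulate_null_delta(design, d, d, n_reps)
    qs <- purrr::map(levels, function(l) {
      stats::quantile(dl, c((1 - l) / 2, (1 + l) / 2), names = FALSE, type = 7)
    })
    vals <- unlist(qs)
    names(vals) <- unlist(purrr::map(levels, function(l) {
      sprintf(c("lo%g", "hi%g"), round(l * 100))
    }))
    dplyr::bind_cols(tibble(depth = d), tibble::as_tibble_row(vals))
  })
  out <- purrr::list_rbind(rows)
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "design") <- design
  class(out) <- unique(c("ci_table", class(out)))
  out
}

#' Write/read a CI table as TSV
#' @param ci A `ci_table`.
#' @param path File path.
#' @export
write_ci_tsv <- function(ci, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- attr(ci, "design")
  writeLines(sprintf("# bsaqtl ci_table: design=%s k=%d error_rate=%g n_reps=%d seed=%s",
                     d$generation %||% "?", d$k %||% NA_integer_,
                     d$error_rate %||% NA_real_,
                     attr(ci, "n_reps") %||% NA_integer_,
                     format(attr(ci, "seed") %||% "none")), con)
  writeLines(paste0("#", paste(names(ci), collapse = "\t")), con)
  readr::write_tsv(as.data.frame(ci), con, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_ci_tsv
#' @export
read_ci_tsv <- function(path) {
  lines <- readLines(path)
  hdr_i <- max(grep("^#", lines))
  cols <- strsplit(sub("^#", "", lines[hdr_i]), "\t")[[1]]
  df <- readr::read_tsv(path, skip = hdr_i, col_names = cols,
                        col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  class(df) <- unique(c("ci_table", class(df)))
  df
}

# clamp arbitrary depths to the nearest tabulated depth (ties -> smaller)
.nearest_depth_index <- function(depth, tab_depths) {
  vapply(depth, function(d) which.min(abs(tab_depths - d)), integer(1))
}

#' Attach null confidence bounds to windows
#'
#' Looks up each SNP's bounds at its observed depth (the conservative
#' `min(lsb_depth, hsb_depth)`, clamped to the nearest tabulated depth) and
#' sets each window's bound to the unweighted mean of the per-SNP bounds of
#' the SNPs inside it — the same averaging used for the window's
#' delta(SNP-index). Windows without SNPs carry `NA` bounds.
#'
#' @param windows A `window_stats` tibble ([sliding_windows()]).
#' @param sites The `snp_index_table` the windows were computed from.
#' @param ci A `ci_table` ([build_ci_table()]).
#' @return `windows` with the CI bound columns of `ci` appended.
#' @export
attach_ci <- function(windows, sites, ci) {
  bound_cols <- setdiff(names(ci), "depth")
  per_site_depth <- pmin(sites$lsb_depth, sites$hsb_depth)
  idx <- .nearest_depth_index(per_site_depth, ci$depth)
  site_bounds <- purrr::map(bound_cols, function(bc) ci[[bc]][idx])
  names(site_bounds) <- bound_cols

  pieces <- purrr::map(unique(windows$chrom), function(ch) {
    w <- windows[windows$chrom == ch, ]
    s_sel <- which(sites$chrom == ch)
    pos <- sites$pos[s_sel]
    ri <- range_indices(pos, w$start, w$end)
    for (bc in bound_cols) {
      w[[bc]] <- windowed_mean(site_bounds[[bc]][s_sel], ri$lo, ri$hi, ri$n)
    }
    w
  })
  out <- purrr::list_rbind(pieces)
  class(out) <- unique(c("window_stats", class(out)))
  out
}
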