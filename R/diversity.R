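#' Haplotype matrices for diversity analysis
#'
#' A haplotype matrix is a tibble whose first two columns are `accession`
#' and `group` and whose remaining columns are sites (one allele call per
#' accession; `NA` = missing). Heterozygous or ambiguous calls (anything
#' other than a single `A`/`C`/`G`/`T` or `0`/`1`) are treated as missing —
#' appropriate for a predominantly selfing species where residual
#' heterozygosity is rare — and their count is recorded in
#' `attr(x, "n_het_masked")`.
#'
#' @param x A data frame in the layout above.
#' @return The cleaned haplotype tibble.
#' @export
as_haplotypes <- function(x) {
  stopifnot(all(c("accession", "group") %in% names(x)))
  site_cols <- setdiff(names(x), c("accession", "group"))
  ok <- c("A", "C", "G", "T", "0", "1")
  masked <- 0L
  for (sc in site_cols) {
    v <- toupper(as.character(x[[sc]]))
    bad <- !is.na(v) & !(v %in% ok)
    masked <- masked + sum(bad)
    v[bad] <- NA_character_
    x[[sc]] <- v
  }
  x <- tibble::as_tibble(x)
  attr(x, "n_het_masked") <- masked
  class(x) <- unique(c("haplotypes", class(x)))
  x
}

#' Read an aligned FASTA as a haplotype matrix
#'
#' @param path Aligned FASTA (equal-length sequences, one per accession).
#' @param groups Named character vector mapping accession ids to group
#'   labels; unnamed accessions get group `"ungrouped"`.
#' @return A `haplotypes` tibble with one column per alignment position
#'   (`p1`, `p2`, ...).
#' @export
read_haplotypes_fasta <- function(path, groups = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_haplotypes_fasta() needs the Biostrings package.")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  L <- unique(Biostrings::width(seqs))
  if (length(L) != 1L) abort("sequences must be aligned (equal length).")
  mat <- do.call(rbind, strsplit(as.character(seqs), ""))
  mat[mat %in% c("-", "N", "n")] <- NA_character_
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- sprintf("p%d", seq_len(L))
  acc <- names(seqs)
  df <- cbind(accession = acc,
              group = unname((groups[acc]) %||% rep(NA_character_, length(acc))),
              df)
  df$group[is.na(df$group)] <- "ungrouped"
  as_haplotypes(df)
}

#' Read a haplotype matrix from TSV
#'
#' @param path TSV with columns `accession`, `group`, then one column per
#'   site.
#' @return A `haplotypes` tibble.
#' @export
read_haplotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  as_haplotypes(df)
}

.hap_matrix <- function(hap, group = NULL) {
  if (!is.null(group)) hap <- hap[hap$group %in% group, ]
  site_cols <- setdiff(names(hap), c("accession", "group"))
  m <- as.matrix(hap[, site_cols, drop = FALSE])
  rownames(m) <- hap$accession
  m
}

#' Average pairwise nucleotide diversity (theta-pi)
#'
#' For every pair of accessions, the fraction of differing sites among the
#' sites called in both members of the pair (pairwise-complete deletion);
#' theta-pi is the average of that fraction over all pairs — a per-site
#' estimate.
#'
#' @param hap A `haplotypes` tibble.
#' @param group Optional group label(s) to subset to.
#' @return Per-site theta-pi (scalar); `NA` with a warning if fewer than
#'   two accessions.
#' @export
theta_pi <- function(hap, group = NULL) {
  m <- .hap_matrix(hap, group)
  n <- nrow(m)
  if (n < 2L) {
    warn("theta_pi is undefined for fewer than 2 accessions.")
    return(NA_real_)
  }
  tot <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(m[i, ]) & !is.na(m[j, ])
      nc <- sum(both)
      if (nc > 0L) {
        tot <- tot + sum(m[i, both] != m[j, both]) / nc
      }
      npair <- npair + 1L
    }
  }
  tot / npair
}

#' Watterson's estimator (theta-w)
#'
#' `theta_w = S / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`, where `S` is
#' the number of segregating sites among `n` sampled haplotypes over a
#' region of `L` bp.
#'
#' @param S Number of segregating sites.
#' @param n Number of sampled haplotypes (>= 2).
#' @param L Region length in bp.
#' @return Per-site theta-w.
#' @export
#' @examples
#' theta_w(3, 4, 100)  # 3 / ((1 + 1/2 + 1/3) * 100)
theta_w <- function(S, n, L) {
  if (n < 2) {
    warn("theta_w is undefined for n < 2.")
    return(NA_real_)
  }
  if (L < 1 || S < 0) abort("require L >= 1 and S >= 0.")
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * L)
}

# sites with >= 2 distinct non-missing alleles within a set of rows
.segregating <- function(m) {
  apply(m, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2L
  })
}

#' Group-private SNP detection
#'
#' A SNP is private to a group when it is polymorphic within that group and
#' monomorphic (at most one observed allele) in every other group.
#'
#' @param hap A `haplotypes` tibble with at least two groups (a single
#'   group makes every polymorphic site trivially private to it).
#' @return A tibble with one row per site: `site`, `polymorphic_in`
#'   (comma-separated group labels), `private_to` (`NA` unless private to
#'   exactly one group).
#' @export
group_private_snps <- function(hap) {
  site_cols <- setdiff(names(hap), c("accession", "group"))
  groups <- unique(hap$group)
  poly <- vapply(groups, function(g) .segregating(.hap_matrix(hap, g)),
                 logical(length(site_cols)))
  if (length(site_cols) == 1L) poly <- matrix(poly, nrow = 1L)
  tibble(
    site = site_cols,
    polymorphic_in = apply(poly, 1, function(row) {
      paste(groups[row], collapse = ",")
    }),
    private_to = unname(apply(poly, 1, function(row) {
      if (sum(row) == 1L) groups[row] else NA_character_
    }))
  )
}

#' Per-group diversity report
#'
#' Computes, for each accession group, the number of accessions, the count
#' of segregating sites `S`, per-site theta-pi and Watterson's theta-w
#' (with `L` the full region length in bp), plus the table of group-private
#' SNPs — the layout used to contrast cultivated against wild germplasm.
#'
#' @param hap A `haplotypes` tibble.
#' @param region_length_bp Total region length `L` (bp); defaults to the
#'   number of site columns (fully genotyped region).
#' @return A list of class `diversity_report`: `groups` (tibble with
#'   `group`, `n`, `S`, `theta_pi`, `theta_w`), `private` (tibble).
#' @export
diversity_report <- function(hap, region_length_bp = NULL) {
  site_cols <- setdiff(names(hap), c("accession", "group"))
  L <- region_length_bp %||% length(site_cols)
  groups <- unique(hap$group)
  gtab <- purrr::map(groups, function(g) {
    m <- .hap_matrix(hap, g)
    S <- sum(.segregating(m))
    tibble(group = g, n = nrow(m), S = S,
           theta_pi = if (nrow(m) >= 2) theta_pi(hap, g) else NA_real_,
           theta_w = if (nrow(m) >= 2) theta_w(S, nrow(m), L) else NA_real_)
  }) |> purrr::list_rbind()
  structure(list(groups = gtab, private = group_private_snps(hap),
                 region_length_bp = L),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("<diversity_report> region %d bp\n", x$region_length_bp))
  print(x$groups)
  npriv <- sum(!is.na(x$private$private_to))
  cat(sprintf("  group-private SNPs: %d\n", npriv))
  invisible(x)
}
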