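#' Read a per-site allele-depth table from TSV
#'
#' The TSV dialect is tab-separated with a single `#`-prefixed header line
#' naming the columns `chrom pos ref alt qual` followed by `<sample>_ref`
#' and `<sample>_alt` depth pairs for the samples `lsb`, `hsb`, `lp` (low
#' parent) and `hp` (high parent) — the format written by
#' [write_counts_tsv()] and by the synthetic-data generator.
#'
#' @param path Input file.
#' @return A `count_table` tibble sorted by (chrom, pos).
#' @export
read_counts_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    abort(sprintf("%s: expected a '#'-prefixed header line.", path))
  }
  cols <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  df <- readr::read_tsv(path, skip = 1L, col_names = cols,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          ref = readr::col_character(),
                          alt = readr::col_character(),
                          .default = readr::col_double()),
                        progress = FALSE)
  depth_cols <- grep("_(ref|alt)$", cols, value = TRUE)
  for (cc in depth_cols) {
    bad <- which(is.na(df[[cc]]) | df[[cc]] < 0 | df[[cc]] != floor(df[[cc]]))
    if (length(bad)) {
      abort(sprintf("%s line %d: column '%s' must be a non-negative integer.",
                    path, bad[1] + 1L, cc))
    }
  }
  df <- dplyr::arrange(df, .data$chrom, .data$pos)
  class(df) <- c("count_table", class(df))
  df
}

#' Write a count table as TSV
#' @param x A `count_table`.
#' @param path Output file.
#' @param comments Optional character vector of extra `#` comment lines
#'   written above the header.
#' @export
write_counts_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  readr::write_tsv(as.data.frame(x), con, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read bulk/parent allele depths from a VCF
#'
#' Parses a VCF (4.2) with per-sample `AD` genotype subfields. Only
#' biallelic SNP records are kept; multi-allelic lines, indels and lines
#' with missing `AD` are skipped and counted (see `attr(x, "skipped")`).
#'
#' @param path VCF file.
#' @param sample_names Named character vector mapping the roles `lsb`,
#'   `hsb`, `low_parent`, `high_parent` to VCF sample column names.
#' @return A `count_table` tibble (same columns as [read_counts_tsv()]).
#' @export
read_counts_vcf <- function(path,
                            sample_names = c(lsb = "LSB", hsb = "HSB",
                                             low_parent = "LOW_PARENT",
                                             high_parent = "HIGH_PARENT")) {
  roles <- c("lsb", "hsb", "low_parent", "high_parent")
  if (!all(roles %in% names(sample_names))) {
    abort("`sample_names` must name all of lsb, hsb, low_parent, high_parent.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_samples <- colnames(v@gt)[-1]
  for (r in roles) {
    if (!sample_names[[r]] %in% gt_samples) {
      abort(sprintf("sample '%s' (role %s) not found in %s.",
                    sample_names[[r]], r, path))
    }
  }

  n_in <- nrow(fix)
  if (n_in == 0L) {
    out <- tibble(chrom = character(), pos = numeric(), ref = character(),
                  alt = character(), qual = numeric(),
                  lsb_ref = numeric(), lsb_alt = numeric(),
                  hsb_ref = numeric(), hsb_alt = numeric(),
                  lp_ref = numeric(), lp_alt = numeric(),
                  hp_ref = numeric(), hp_alt = numeric())
    attr(out, "skipped") <- 0L
    class(out) <- c("count_table", class(out))
    return(out)
  }

  ad <- vcfR::extract.gt(v, element = "AD")
  biallelic_snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$ALT %in% c("A", "C", "G", "T")
  ad_ok <- rowSums(is.na(ad[, sample_names[roles], drop = FALSE]) |
                     ad[, sample_names[roles], drop = FALSE] == ".") == 0
  keep <- biallelic_snp & ad_ok
  skipped <- sum(!keep)

  split_ad <- function(col) {
    parts <- strsplit(ad[keep, col], ",", fixed = TRUE)
    list(ref = as.numeric(vapply(parts, `[`, "", 1L)),
         alt = as.numeric(vapply(parts, function(p) p[2] %||% "0", "")))
  }
  sl <- split_ad(sample_names[["lsb"]])
  sh <- split_ad(sample_names[["hsb"]])
  sp <- split_ad(sample_names[["low_parent"]])
  sq <- split_ad(sample_names[["high_parent"]])

  out <- tibble(
    chrom = fix$CHROM[keep], pos = as.numeric(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    lsb_ref = sl$ref, lsb_alt = sl$alt,
    hsb_ref = sh$ref, hsb_alt = sh$alt,
    lp_ref = sp$ref, lp_alt = sp$alt,
    hp_ref = sq$ref, hp_alt = sq$alt
  ) |> dplyr::arrange(.data$chrom, .data$pos)
  attr(out, "skipped") <- skipped
  class(out) <- c("count_table", class(out))
  out
}

#' Write a count table as a minimal VCF 4.2 with AD fields
#'
#' @param x A `count_table`.
#' @param path Output file.
#' @param contig_lengths Optional named vector of chromosome lengths for the
#'   header.
#' @export
write_counts_vcf <- function(x, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsaqtl",
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT",
                        "LSB", "HSB", "LOW_PARENT", "HIGH_PARENT"),
                      collapse = "\t"))
  ad <- function(r, a) sprintf("%d,%d", as.integer(r), as.integer(a))
  body <- paste(x$chrom, as.integer(x$pos), ".", x$ref, x$alt, x$qual,
                "PASS", ".", "AD",
                ad(x$lsb_ref, x$lsb_alt), ad(x$hsb_ref, x$hsb_alt),
                ad(x$lp_ref, x$lp_alt), ad(x$hp_ref, x$hp_alt),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Polarize sites to the high-parent allele
#'
#' Keeps only sites where the two parents are fixed for opposite alleles
#' (each parent: at least `fixed_frac` of its reads on one allele, with
#' parent depth at least `min_parent_depth`) and re-expresses both bulks'
#' counts in terms of the high-parent allele. Downstream SNP-index is then
#' 0 when every read carries the low-parent allele and 1 when every read
#' carries the high-parent allele, regardless of which parent matches the
#' reference genome.
#'
#' @param counts A `count_table`.
#' @param fixed_frac Minimum fraction of a parent's reads on its major
#'   allele for the parent to count as fixed (default 0.9).
#' @param min_parent_depth Minimum parent depth for a confident parental
#'   genotype (default 10).
#' @return A `polarized_sites` tibble: `chrom`, `pos`, `qual`,
#'   `high_is_ref`, `lsb_high`, `lsb_depth`, `hsb_high`, `hsb_depth`.
#'   Attribute `n_dropped` counts non-informative sites removed.
#' @export
polarize <- function(counts, fixed_frac = 0.9, min_parent_depth = 10) {
  need <- c("lp_ref", "lp_alt", "hp_ref", "hp_alt")
  if (!all(need %in% names(counts))) {
    abort("parent depth columns (lp_*/hp_*) are required for polarization.")
  }
  lp_d <- counts$lp_ref + counts$lp_alt
  hp_d <- counts$hp_ref + counts$hp_alt
  lp_ref_frac <- ifelse(lp_d > 0, counts$lp_ref / lp_d, NA_real_)
  hp_ref_frac <- ifelse(hp_d > 0, counts$hp_ref / hp_d, NA_real_)

  lp_fixed_ref <- lp_d >= min_parent_depth & lp_ref_frac >= fixed_frac
  lp_fixed_alt <- lp_d >= min_parent_depth & (1 - lp_ref_frac) >= fixed_frac
  hp_fixed_ref <- hp_d >= min_parent_depth & hp_ref_frac >= fixed_frac
  hp_fixed_alt <- hp_d >= min_parent_depth & (1 - hp_ref_frac) >= fixed_frac

  # opposite fixed alleles: exactly one of the two orientations
  high_is_ref <- hp_fixed_ref & lp_fixed_alt
  high_is_alt <- hp_fixed_alt & lp_fixed_ref
  keep <- !is.na(high_is_ref) & !is.na(high_is_alt) & (high_is_ref | high_is_alt)

  x <- counts[which(keep), ]
  hr <- high_is_ref[which(keep)]
  out <- tibble(
    chrom = x$chrom, pos = x$pos, qual = x$qual,
    high_is_ref = hr,
    lsb_high = ifelse(hr, x$lsb_ref, x$lsb_alt),
    lsb_depth = x$lsb_ref + x$lsb_alt,
    hsb_high = ifelse(hr, x$hsb_ref, x$hsb_alt),
    hsb_depth = x$hsb_ref + x$hsb_alt
  )
  attr(out, "n_dropped") <- sum(!keep, na.rm = TRUE) + sum(is.na(keep))
  class(out) <- c("polarized_sites", class(out))
  out
}

#' Apply the site depth and quality filters
#'
#' A site survives iff its depth is at least `min_depth` in *both* bulks and
#' its call quality is at least `min_quality` (boundaries inclusive). The
#' operation is idempotent and its output is always a subset of its input.
#'
#' @param sites A `polarized_sites` tibble.
#' @param min_depth Minimum per-bulk depth (default 10).
#' @param min_quality Minimum phred-scaled site quality (default 20).
#' @return The filtered tibble; attribute `n_removed` counts drops.
#' @export
filter_sites <- function(sites, min_depth = 10, min_quality = 20) {
  if (min_depth < 0 || min_quality < 0) abort("thresholds must be >= 0.")
  keep <- sites$lsb_depth >= min_depth & sites$hsb_depth >= min_depth &
    (is.na(sites$qual) | sites$qual >= min_quality)
  keep[is.na(keep)] <- FALSE
  out <- sites[keep, ]
  attr(out, "n_dropped") <- attr(sites, "n_dropped")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- unique(c("polarized_sites", class(out)))
  out
}
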