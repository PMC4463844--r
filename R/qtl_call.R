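#' Call candidate QTL intervals from windowed statistics
#'
#' A window is *significant* when its delta(SNP-index) falls outside its
#' simulated null confidence bound at the chosen level, and — when the
#' bulk-index criteria are enabled — its mean high-bulk SNP-index is at
#' least `hsb_min` (default 0.9) and its mean low-bulk SNP-index at most
#' `lsb_max` (default 0.1). Runs of at least `min_run` consecutive
#' significant windows on a chromosome are merged into intervals whose
#' boundaries are the outermost window endpoints of the run.
#'
#' @param windows A `window_stats` tibble with CI bounds attached
#'   ([attach_ci()]).
#' @param level Significance level, 0.95 or 0.99 (must be tabulated in the
#'   bounds columns).
#' @param hsb_min,lsb_max Bulk-index thresholds; set `use_index_criteria =
#'   FALSE` to call on the CI alone.
#' @param min_run Minimum number of consecutive significant windows
#'   (default 2, suppressing single-window noise).
#' @param abs_delta_min Optional absolute delta(SNP-index) floor (default
#'   off).
#' @param use_index_criteria Apply the `hsb_min`/`lsb_max` thresholds
#'   (default TRUE).
#' @return A `qtl_intervals` tibble: `chrom`, `start`, `end`, `length_bp`
#'   (plain difference of the flanking coordinates), `n_windows`,
#'   `peak_delta`, `peak_pos`, `hsb_index`, `lsb_index`, `level_attained`.
#' @export
call_intervals <- function(windows, level = 0.95, hsb_min = 0.9,
                           lsb_max = 0.1, min_run = 2,
                           abs_delta_min = NULL, use_index_criteria = TRUE) {
  lo_col <- sprintf("lo%g", round(level * 100))
  hi_col <- sprintf("hi%g", round(level * 100))
  if (!all(c(lo_col, hi_col) %in% names(windows))) {
    abort(sprintf("windows carry no %g%% bounds; run attach_ci() first.",
                  level * 100))
  }
  has99 <- all(c("lo99", "hi99") %in% names(windows))

  sig <- !is.na(windows$delta) & !is.na(windows[[lo_col]]) &
    (windows$delta < windows[[lo_col]] | windows$delta > windows[[hi_col]])
  if (use_index_criteria) {
    sig <- sig & !is.na(windows$hsb_index) &
      windows$hsb_index >= hsb_min & windows$lsb_index <= lsb_max
  }
  if (!is.null(abs_delta_min)) {
    sig <- sig & abs(windows$delta) >= abs_delta_min
  }

  pieces <- purrr::map(unique(windows$chrom), function(ch) {
    wsel <- which(windows$chrom == ch)
    w <- windows[wsel, ]
    s <- sig[wsel]
    if (!any(s)) return(NULL)
    r <- rle(s)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_run)
    purrr::map(runs, function(ri) {
      i0 <- starts_i[ri]; i1 <- ends_i[ri]
      ww <- w[i0:i1, ]
      pk <- which.max(abs(ww$delta))
      lev <- level * 100
      if (has99 && all(ww$delta < ww$lo99 | ww$delta > ww$hi99)) lev <- 99
      tibble(chrom = ch, start = min(ww$start), end = max(ww$end),
             length_bp = max(ww$end) - min(ww$start),
             n_windows = nrow(ww),
             peak_delta = ww$delta[pk], peak_pos = ww$midpoint[pk],
             hsb_index = mean(ww$hsb_index), lsb_index = mean(ww$lsb_index),
             level_attained = lev)
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(purrr::compact(pieces))
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  length_bp = numeric(), n_windows = integer(),
                  peak_delta = numeric(), peak_pos = numeric(),
                  hsb_index = numeric(), lsb_index = numeric(),
                  level_attained = numeric())
  }
  class(out) <- unique(c("qtl_intervals", class(out)))
  out
}

#' Physical and genetic interval lengths
#'
#' Physical length is the plain difference of the two flanking coordinates
#' (`end - start`, bp) — the convention used when an interval is reported by
#' its flanking markers. Genetic length is the absolute difference of two
#' map positions in centimorgans.
#'
#' @param start,end Flanking physical coordinates (bp).
#' @return Length in bp.
#' @export
#' @examples
#' interval_length(5537208, 5676601)  # 139393
#' interval_length(836859, 872247)    # 35388, i.e. ~35 kb
interval_length <- function(start, end) {
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    abort("coordinates must be finite.")
  }
  end - start
}

#' @rdname interval_length
#' @param pos_a_cM,pos_b_cM Flanking genetic map positions (cM).
#' @return Genetic length in cM.
#' @export
#' @examples
#' genetic_length(3.7, 5.5)  # 1.8
genetic_length <- function(pos_a_cM, pos_b_cM) {
  if (any(!is.finite(pos_a_cM)) || any(!is.finite(pos_b_cM))) {
    abort("coordinates must be finite.")
  }
  abs(pos_b_cM - pos_a_cM)
}

#' Genes overlapping a QTL interval
#'
#' Reads gene features from a GFF3 file and returns the ids of genes whose
#' span overlaps the interval by at least 1 bp, on either strand (1-based
#' inclusive coordinates; a gene starting exactly at the interval end is
#' included).
#'
#' @param gff_path Path to a GFF3 file with `gene` features.
#' @param chrom,start,end The interval.
#' @return Character vector of gene ids (the GFF `ID`, falling back to
#'   `Name`).
#' @export
genes_in_interval <- function(gff_path, chrom, start, end) {
  if (!file.exists(gff_path)) {
    abort(sprintf("GFF file not found: %s", gff_path))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("genes_in_interval() needs the rtracklayer package.")
  }
  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e) {
                   abort(sprintf("could not read GFF %s: %s", gff_path,
                                 conditionMessage(e)))
                 })
  if (length(gr) == 0L) return(character())
  genes <- gr[!is.na(gr$type) & gr$type == "gene"]
  if (length(genes) == 0L) return(character())
  g_chrom <- as.character(GenomicRanges::seqnames(genes))
  g_start <- GenomicRanges::start(genes)
  g_end <- GenomicRanges::end(genes)
  hit <- g_chrom == chrom & g_start <= end & g_end >= start
  ids <- genes$ID
  if (is.null(ids)) ids <- genes$Name
  if (is.null(ids)) ids <- sprintf("gene_%d", seq_along(genes))
  ids[is.na(ids)] <- (genes$Name %||% rep(NA_character_, length(genes)))[is.na(ids)]
  as.character(ids[hit])
}

#' Write intervals as BED (0-based half-open) and as a TSV report
#'
#' @param intervals A `qtl_intervals` tibble.
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @export
write_intervals <- function(intervals, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = intervals$chrom,
                      start = as.integer(intervals$start) - 1L,
                      end = as.integer(intervals$end),
                      name = sprintf("qtl_%d", seq_len(nrow(intervals))),
                      score = round(abs(intervals$peak_delta) * 1000))
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(as.data.frame(intervals), tsv_path, progress = FALSE)
  }
  invisible(intervals)
}
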