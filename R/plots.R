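#' Plot a QTL-seq genome scan
#'
#' Draws, per chromosome, the windowed high- and low-bulk SNP-index tracks
#' and the delta(SNP-index) track with its simulated null confidence band;
#' called intervals are shaded.
#'
#' @param object A `qtlseq_result`.
#' @param level Which band to draw (95 or 99, default matches the call
#'   level).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtlseq_result
#' @export
autoplot.qtlseq_result <- function(object, level = NULL, ...) {
  level <- level %||% (object$params$level * 100)
  lo <- sprintf("lo%g", round(level))
  hi <- sprintf("hi%g", round(level))
  w <- object$windows |>
    dplyr::filter(!.data$low_snps) |>
    dplyr::mutate(mb = .data$midpoint / 1e6)
  long <- w |>
    dplyr::select("chrom", "mb", "lsb_index", "hsb_index", "delta") |>
    tidyr::pivot_longer(c("lsb_index", "hsb_index", "delta"),
                        names_to = "track", values_to = "value") |>
    dplyr::mutate(track = factor(.data$track,
                                 levels = c("hsb_index", "lsb_index", "delta"),
                                 labels = c("HSB SNP-index", "LSB SNP-index",
                                            "Δ(SNP-index)")))
  band <- w |>
    dplyr::mutate(track = factor("Δ(SNP-index)",
                                 levels = levels(long$track)),
                  lo = .data[[lo]], hi = .data[[hi]])

  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mb, y = .data$value)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$mb, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(track ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$intervals)) {
    iv <- object$intervals |>
      dplyr::mutate(x0 = .data$start / 1e6, x1 = .data$end / 1e6)
    p <- p + ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.15)
  }
  p
}

#' Histogram of per-individual trait means with parental markers
#'
#' @param pheno A phenotype tibble.
#' @param parent_means Named `c(low=, high=)` parental means, drawn as
#'   dashed lines.
#' @param bins Histogram bins (default 20).
#' @return A ggplot object.
#' @export
plot_trait_distribution <- function(pheno, parent_means = c(low = 8.9,
                                                            high = 30.1),
                                    bins = 20) {
  im <- individual_means(pheno)
  ggplot2::ggplot(im, ggplot2::aes(x = .data$mean_value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = unname(parent_means),
                        linetype = "dashed") +
    ggplot2::labs(x = "trait mean per individual", y = "count") +
    ggplot2::theme_minimal()
}
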