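#' Specify a (single) causal quantitative trait locus
#'
#' The trait model is `value = baseline + a * (dosage - 1) + d * [het]` plus
#' environment and residual terms added by [simulate_phenotypes()]. With the
#' defaults, homozygotes for the low- and high-parent alleles have genetic
#' values equal to the two parental means (8.9 g and 30.1 g 100-seed weight),
#' i.e. a fully additive major locus with `a = (high - low) / 2`.
#'
#' @param chrom,pos Location of the causal site; must coincide with a site of
#'   the SNP map used for breeding.
#' @param parent_means Named numeric `c(low=, high=)` genetic values of the
#'   two parental homozygotes, in trait units (g).
#' @param additive Additive effect per high allele (g); default
#'   `(high - low) / 2`.
#' @param dominance Dominance deviation of the heterozygote (g); default 0.
#' @param h2 Target broad-sense heritability on the entry-mean basis, in
#'   (0, 1].
#' @return A list of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, pos, parent_means = c(low = 8.9, high = 30.1),
                     additive = NULL, dominance = 0, h2 = 0.85) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 > 1) {
    abort("`h2` must lie in (0, 1]; a zero-heritability model is degenerate.")
  }
  stopifnot(all(c("low", "high") %in% names(parent_means)))
  additive <- additive %||% (unname(parent_means["high"] - parent_means["low"]) / 2)
  structure(list(chrom = chrom, pos = pos,
                 parent_means = parent_means,
                 baseline = mean(parent_means),
                 additive = additive, dominance = dominance, h2 = h2),
            class = "qtl_spec")
}

#' Simulate replicated multi-environment phenotypes
#'
#' Generates a balanced trial: every individual is scored in
#' `n_environments` environments with `n_replicates` replicates each.
#' Genetic value comes from the QTL model in [qtl_spec()]; environments
#' contribute additive shifts (drawn once, centred to sum to zero, so an
#' individual's mean over the whole balanced trial equals its genetic value
#' in expectation-free form when `h2 = 1`); residuals are iid normal with
#' variance solved so that the entry-mean broad-sense heritability
#' `Vg / (Vg + Ve / (e * r))` equals the target `h2`.
#'
#' If the population is monomorphic at the causal site (no genetic variance)
#' the residual standard deviation falls back to `resid_sd_fallback` and all
#' variation is environmental.
#'
#' @param geno A `geno_matrix` from [breed_f4()].
#' @param qtl A [qtl_spec()]; its position must be a map site. `NULL`
#'   simulates a no-QTL (null) trait: pure environment + noise around the
#'   mid-parent value.
#' @param n_environments,n_replicates Trial dimensions (defaults 3 and 2:
#'   three year-location environments, two replicates).
#' @param env_sd Standard deviation of environment main effects (g).
#' @param resid_sd_fallback Residual sd (g) used when genetic variance is
#'   zero (monomorphic causal site or `qtl = NULL`).
#' @param seed Optional integer seed.
#' @return A tibble (`pheno_table`) with columns `individual`,
#'   `environment`, `replicate`, `value`, and attributes `genetic_values`
#'   (named vector) and `target_h2`.
#' @export
simulate_phenotypes <- function(geno, qtl, n_environments = 3,
                                n_replicates = 2, env_sd = 1,
                                resid_sd_fallback = 2, seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  e <- assert_count(n_environments, "n_environments", min = 1L)
  r <- assert_count(n_replicates, "n_replicates", min = 1L)
  with_seed(seed)

  n <- nrow(geno$dosage)
  if (is.null(qtl)) {
    g <- rep(19.5, n)
    h2 <- NA_real_
  } else {
    stopifnot(inherits(qtl, "qtl_spec"))
    ci <- site_index(geno$map, qtl$chrom, qtl$pos)
    dos <- geno$dosage[, ci]
    g <- qtl$baseline + qtl$additive * (dos - 1) +
      qtl$dominance * (dos == 1L)
    h2 <- qtl$h2
  }
  names(g) <- geno$individuals

  vg <- stats::var(g)
  if (is.na(h2) || vg == 0) {
    resid_sd <- resid_sd_fallback
  } else if (h2 == 1) {
    resid_sd <- 0
  } else {
    # entry-mean H2 = Vg / (Vg + Ve/(e*r))  =>  Ve = Vg (1/H2 - 1) e r
    resid_sd <- sqrt(vg * (1 / h2 - 1) * e * r)
  }

  env_eff <- rnorm(e, 0, env_sd)
  env_eff <- env_eff - mean(env_eff)  # centred: balanced means are unbiased

  out <- tidyr::expand_grid(
    individual = geno$individuals,
    environment = sprintf("E%d", seq_len(e)),
    replicate = sprintf("R%d", seq_len(r))
  )
  out$value <- g[out$individual] +
    env_eff[as.integer(sub("^E", "", out$environment))] +
    rnorm(nrow(out), 0, resid_sd)

  attr(out, "genetic_values") <- g
  attr(out, "target_h2") <- h2
  class(out) <- c("pheno_table", class(out))
  out
}

#' Per-individual trait means across environments and replicates
#'
#' @param pheno A phenotype tibble with `individual` and `value` columns.
#' @return A tibble `individual`, `mean_value`, sorted by individual id.
#' @export
individual_means <- function(pheno) {
  pheno |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$individual)
}
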