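#' Goodness-of-fit filter for marker segregation
#'
#' Tests the homozygous genotype classes of one marker against the expected
#' Mendelian 1:1 ratio with a Pearson chi-square (df = classes - 1, no
#' continuity correction). Heterozygotes are excluded: in a selfing
#' population advanced by single-seed descent the informative segregation
#' contrast is between the two homozygous classes.
#'
#' @param genotypes Character vector of genotype codes (`"LL"`, `"LH"`,
#'   `"HH"`) for one marker.
#' @param expected_ratio Numeric length-2 expected ratio of LL : HH
#'   (default `c(1, 1)`).
#' @param alpha Rejection level (default 0.05).
#' @return A one-row tibble: `n_LL`, `n_HH`, `n_het_excluded`, `chisq`,
#'   `df`, `p_value`, `pass`.
#' @export
#' @examples
#' segregation_filter(rep(c("LL", "HH"), c(60, 40)))  # chisq = 4, fail
segregation_filter <- function(genotypes, expected_ratio = c(1, 1),
                               alpha = 0.05) {
  obs <- c(LL = sum(genotypes == "LL"), HH = sum(genotypes == "HH"))
  n_het <- sum(genotypes == "LH")
  total <- sum(obs)
  if (total == 0L) abort("no homozygous genotype calls at this marker.")
  exp_p <- expected_ratio / sum(expected_ratio)
  expd <- total * exp_p
  chisq <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  tibble(n_LL = obs[["LL"]], n_HH = obs[["HH"]], n_het_excluded = n_het,
         chisq = chisq, df = df, p_value = p, pass = p >= alpha)
}

#' Single-marker association scan
#'
#' Regresses the per-individual mean phenotype on the high-allele dosage
#' (0/1/2) at every marker. Reports the percent phenotypic variance
#' explained `R2 = 100 (1 - RSS1/RSS0)`, the LOD score
#' `(n/2) log10(RSS0/RSS1)`, the additive effect
#' `a = (mean_HH - mean_LL) / 2`, and genotype class means. Monomorphic
#' markers are flagged and carry `NA` statistics.
#'
#' @param geno A `geno_matrix`.
#' @param pheno A phenotype tibble covering the same individuals.
#' @return A `marker_scan` tibble with one row per marker: `marker`,
#'   `chrom`, `pos`, `r_squared` (percent), `lod`, `additive`, `mean_LL`,
#'   `mean_LH`, `mean_HH`, `monomorphic`.
#' @export
single_marker_scan <- function(geno, pheno) {
  stopifnot(inherits(geno, "geno_matrix"))
  ym <- individual_means(pheno)
  shared <- intersect(ym$individual, geno$individuals)
  if (length(shared) < 3L) abort("need at least 3 shared individuals.")
  y <- stats::setNames(ym$mean_value, ym$individual)[shared]
  X <- geno$dosage[shared, , drop = FALSE]
  n <- length(y)

  yc <- y - mean(y)
  ss_y <- sum(yc^2)
  xm <- colMeans(X)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- as.vector(crossprod(X, yc))
  # a constant phenotype explains nothing (R2 = 0); only monomorphic
  # markers leave the association undefined
  r2 <- if (ss_y > 0) sxy^2 / (sxx * ss_y) else rep(0, ncol(X))
  r2[sxx == 0] <- NA_real_
  r2 <- pmin(pmax(r2, 0), 1)
  lod <- -(n / 2) * log10(1 - r2)

  class_mean <- function(code) {
    cnt <- colSums(X == code)
    sums <- as.vector(crossprod(X == code, y))
    ifelse(cnt > 0, sums / cnt, NA_real_)
  }
  m_ll <- class_mean(0L); m_lh <- class_mean(1L); m_hh <- class_mean(2L)

  out <- tibble(
    marker = sprintf("%s_%d", geno$map$sites$chrom, geno$map$sites$pos),
    chrom = geno$map$sites$chrom, pos = geno$map$sites$pos,
    r_squared = 100 * r2, lod = lod,
    additive = (m_hh - m_ll) / 2,
    mean_LL = m_ll, mean_LH = m_lh, mean_HH = m_hh,
    monomorphic = sxx == 0
  )
  class(out) <- unique(c("marker_scan", class(out)))
  out
}

#' Broad-sense heritability from a replicated multi-environment trial
#'
#' Estimates variance components by method of moments from the expected
#' mean squares of the two-way (individual x environment) ANOVA with `r`
#' replicates: `MS_G = Ve + r*Vge + r*e*Vg`, `MS_GE = Ve + r*Vge`,
#' `MS_err = Ve`. Broad-sense heritability on the entry-mean basis is
#' `H2 = Vg / (Vg + Vge/e + Ve/(e*r))`. Negative component estimates are
#' truncated at zero. With a single replicate the interaction and error are
#' confounded and pooled; with a single environment `H2` is undefined.
#'
#' @param pheno Phenotype tibble with `individual`, `environment`,
#'   `replicate`, `value`.
#' @return A list of class `h2_estimate`: `h2`, `var_g`, `var_ge`,
#'   `var_e`, `n_env`, `n_rep`.
#' @export
broad_sense_h2 <- function(pheno) {
  e <- length(unique(pheno$environment))
  if (e < 2L) {
    warn("single environment: broad-sense H2 is undefined.")
    return(structure(list(h2 = NA_real_, var_g = NA_real_, var_ge = NA_real_,
                          var_e = NA_real_, n_env = e, n_rep = NA_real_),
                     class = "h2_estimate"))
  }
  r <- nrow(pheno) / (length(unique(pheno$individual)) * e)
  df <- data.frame(ind = factor(pheno$individual),
                   env = factor(pheno$environment),
                   value = pheno$value)
  if (r > 1) {
    fit <- stats::aov(value ~ ind + env + ind:env, data = df)
    # suppress the "essentially perfect fit" warning: zero residual variance
    # is a legitimate limit here (fully heritable trait)
    tab <- suppressWarnings(anova(fit))
    ms <- tab$`Mean Sq`
    names(ms) <- rownames(tab)
    ms_g <- ms[["ind"]]; ms_ge <- ms[["ind:env"]]; ms_err <- ms[["Residuals"]]
    var_e <- ms_err
    var_ge <- max((ms_ge - ms_err) / r, 0)
    var_g <- max((ms_g - ms_ge) / (r * e), 0)
  } else {
    fit <- stats::aov(value ~ ind + env, data = df)
    tab <- suppressWarnings(anova(fit))
    ms <- tab$`Mean Sq`
    names(ms) <- rownames(tab)
    var_e <- ms[["Residuals"]]  # pooled GxE + error
    var_ge <- 0
    var_g <- max((ms[["ind"]] - var_e) / e, 0)
  }
  denom <- var_g + var_ge / e + var_e / (e * r)
  h2 <- if (denom > 0) var_g / denom else NA_real_
  structure(list(h2 = h2, var_g = var_g, var_ge = var_ge, var_e = var_e,
                 n_env = e, n_rep = r),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("<h2_estimate> H2 = %.3f (Vg %.3f, Vge %.3f, Ve %.3f; %d env x %.3g rep)\n",
              x$h2, x$var_g, x$var_ge, x$var_e, x$n_env, x$n_rep))
  invisible(x)
}

# moment skewness / excess kurtosis with their large-sample z tests
.shape_tests <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  se1 <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se2 <- 2 * se1 * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  tibble(skewness = g1, kurtosis_excess = g2,
         z_skewness = g1 / se1, z_kurtosis = g2 / se2,
         p_skewness = 2 * stats::pnorm(-abs(g1 / se1)),
         p_kurtosis = 2 * stats::pnorm(-abs(g2 / se2)))
}

#' Phenotype summary of a replicated trial
#'
#' Per-environment descriptive statistics (mean, SD, range, CV%), pooled
#' broad-sense heritability ([broad_sense_h2()]), the count of
#' transgressive segregants (individuals whose across-trial mean lies
#' beyond either parental mean), and moment-based normality z-tests of the
#' individual means.
#'
#' @param pheno Phenotype tibble.
#' @param parent_means Named numeric `c(low=, high=)` parental trait means.
#' @return A list of class `pheno_summary`: `by_environment` (tibble),
#'   `h2` (an `h2_estimate`), `transgressive` (list `low`, `high`,
#'   `total`), `normality` (tibble).
#' @export
pheno_summary <- function(pheno, parent_means = c(low = 8.9, high = 30.1)) {
  by_env <- pheno |>
    dplyr::group_by(environment = .data$environment) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     min = min(.data$value), max = max(.data$value),
                     cv_pct = 100 * stats::sd(.data$value) / mean(.data$value),
                     .groups = "drop")
  h2 <- if (length(unique(pheno$environment)) >= 2L) {
    broad_sense_h2(pheno)
  } else {
    suppressWarnings(broad_sense_h2(pheno))
  }
  im <- individual_means(pheno)
  # numeric tolerance so genetic values exactly at a parental mean do not
  # count as transgressive through floating-point round-off
  tol <- 1e-8 * max(abs(parent_means), 1)
  lo <- sum(im$mean_value < min(parent_means) - tol)
  hi <- sum(im$mean_value > max(parent_means) + tol)
  structure(list(by_environment = by_env, h2 = h2,
                 transgressive = list(low = lo, high = hi, total = lo + hi),
                 normality = .shape_tests(im$mean_value)),
            class = "pheno_summary")
}

#' @export
print.pheno_summary <- function(x, ...) {
  cat("<pheno_summary>\n")
  print(x$by_environment)
  cat(sprintf("  H2 = %.3f | transgressive: %d low + %d high\n",
              x$h2$h2, x$transgressive$low, x$transgressive$high))
  invisible(x)
}
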