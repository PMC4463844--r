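#' Breed an F4 population by single-seed descent
#'
#' Simulates a bi-parental cross followed by selfing: every F1 plant is
#' heterozygous at all parent-differentiating sites; each line is then
#' advanced one selfed offspring per generation (single-seed descent) to the
#' requested generation. Meiosis follows the Haldane model: the crossover
#' count per chromosome is Poisson with mean equal to the chromosome's
#' genetic length in Morgans, breakpoints uniform, no interference.
#'
#' Under this model the expected per-site genotype law in an unselected F4 is
#' 7:2:7 (low-homozygote : heterozygote : high-homozygote), heterozygosity
#' halving with every selfing round from the F2's 1/2.
#'
#' @param map A [make_snp_map()] object.
#' @param n_individuals Number of lines to breed (default 221).
#' @param generation Target generation, one of `"F2"`, `"F4"` (default) —
#'   i.e. one or three selfing rounds after the F1.
#' @param seed Optional integer seed.
#'
#' @return An object of class `geno_matrix`: a list with
#'   * `dosage`: integer matrix (individuals x sites) counting high-parent
#'     alleles, 0 = LL, 1 = LH, 2 = HH;
#'   * `individuals`: character ids;
#'   * `map`: the input `snp_map`;
#'   * `generation`: the generation label.
#' @export
breed_f4 <- function(map, n_individuals = 221, generation = c("F4", "F2"),
                     seed = NULL) {
  stopifnot(inherits(map, "snp_map"))
  generation <- match.arg(generation)
  assert_count(n_individuals, "n_individuals", min = 1L)
  if (nrow(map$sites) < 1L) abort("`map` must contain at least one site.")
  with_seed(seed)

  n_self <- if (generation == "F2") 1L else 3L
  m <- nrow(map$sites)
  # two haplotypes per individual; 0 = low-parent allele, 1 = high-parent
  hapA <- matrix(0L, n_individuals, m)
  hapB <- matrix(1L, n_individuals, m)

  chrom_idx <- split(seq_len(m), factor(map$sites$chrom,
                                        levels = map$chromosomes$chrom))
  morgans <- map$chromosomes$length_bp / 1e6 * map$chromosomes$cM_per_Mb / 100

  for (g in seq_len(n_self)) {
    newA <- matrix(0L, n_individuals, m)
    newB <- matrix(0L, n_individuals, m)
    for (i in seq_len(n_individuals)) {
      newA[i, ] <- .gamete(hapA[i, ], hapB[i, ], map, chrom_idx, morgans)
      newB[i, ] <- .gamete(hapA[i, ], hapB[i, ], map, chrom_idx, morgans)
    }
    hapA <- newA
    hapB <- newB
  }

  ids <- sprintf("ind%03d", seq_len(n_individuals))
  dosage <- hapA + hapB
  rownames(dosage) <- ids
  structure(list(dosage = dosage, individuals = ids, map = map,
                 generation = generation),
            class = "geno_matrix")
}

# one meiotic product of a diploid: Haldane crossovers per chromosome
.gamete <- function(a, b, map, chrom_idx, morgans) {
  out <- integer(length(a))
  for (ci in seq_along(chrom_idx)) {
    idx <- chrom_idx[[ci]]
    if (length(idx) == 0L) next
    len <- map$chromosomes$length_bp[ci]
    n_co <- rpois(1L, morgans[ci])
    phase0 <- sample.int(2L, 1L) - 1L
    if (n_co == 0L) {
      out[idx] <- if (phase0 == 0L) a[idx] else b[idx]
    } else {
      breaks <- sort(runif(n_co, 0, len))
      seg <- findInterval(map$sites$pos[idx], breaks)
      phase <- (phase0 + seg) %% 2L
      out[idx] <- ifelse(phase == 0L, a[idx], b[idx])
    }
  }
  out
}

#' Genotype codes as a tidy tibble
#'
#' @param x A `geno_matrix`.
#' @param ... Ignored.
#' @return A tibble with one row per (individual, site):
#'   `individual`, `chrom`, `pos`, `genotype` in `{"LL","LH","HH"}`.
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  codes <- c("LL", "LH", "HH")
  tibble(
    individual = rep(x$individuals, times = ncol(x$dosage)),
    chrom = rep(x$map$sites$chrom, each = nrow(x$dosage)),
    pos = rep(x$map$sites$pos, each = nrow(x$dosage)),
    genotype = codes[as.vector(x$dosage) + 1L]
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %s population: %d individuals x %d sites\n",
              x$generation, nrow(x$dosage), ncol(x$dosage)))
  het <- mean(x$dosage == 1L)
  cat(sprintf("  heterozygote fraction: %.4f\n", het))
  invisible(x)
}

# site index of a (chrom, pos) pair in a map; NULL chrom matches pos alone
site_index <- function(map, chrom, pos) {
  hit <- which(map$sites$chrom == chrom & map$sites$pos == pos)
  if (length(hit) != 1L) {
    abort(sprintf("position %s:%s is not a site of the map", chrom,
                  format(pos, big.mark = ",")))
  }
  hit
}

#' Write genotypes as TSV (individuals x markers, codes LL/LH/HH)
#'
#' @param geno A `geno_matrix`.
#' @param path Output file.
#' @export
write_geno_tsv <- function(geno, path) {
  codes <- c("LL", "LH", "HH")
  g <- matrix(codes[geno$dosage + 1L], nrow = nrow(geno$dosage))
  df <- as.data.frame(g)
  names(df) <- sprintf("%s_%d", geno$map$sites$chrom, geno$map$sites$pos)
  df <- cbind(individual = geno$individuals, df)
  readr::write_tsv(df, path)
  invisible(path)
}
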