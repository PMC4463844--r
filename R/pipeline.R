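#' Simulate a complete bulked-segregant sequencing experiment
#'
#' One call chains the whole generator: SNP map, F4 single-seed-descent
#' breeding, replicated phenotypes under a major-QTL model, extreme-bulk
#' selection and bulk/parent read sampling. Defaults mirror a two-landrace
#' seed-weight cross: 221 F4 individuals, parental 100-seed weights 8.9 g
#' and 30.1 g, bulks of 10, mean depth 30.
#'
#' @param n_chrom,chrom_length_bp,n_sites_per_chrom,cM_per_Mb SNP-map
#'   parameters (see [make_snp_map()]).
#' @param n_individuals Population size (default 221).
#' @param qtl Either a [qtl_spec()], `NULL` for a no-QTL null simulation,
#'   or the default `"auto"`, which places a fully additive QTL at the map
#'   site nearest `qtl_pos_bp` on chromosome 1 with heritability `h2`.
#' @param qtl_pos_bp,h2 Used only when `qtl = "auto"`.
#' @param n_environments,n_replicates,env_sd Trial layout
#'   (see [simulate_phenotypes()]).
#' @param k Bulk size.
#' @param require_homozygous Screen bulk candidates for homozygosity at the
#'   causal site (default FALSE; ignored for null simulations).
#' @param mean_depth,error_rate Read model (see [sequence_bulks()]).
#' @param seed Integer seed driving every stage.
#' @return A list of class `bsa_sim`: `map`, `geno`, `pheno`, `bulks`,
#'   `counts`, `qtl`, `realized_h2`.
#' @export
simulate_cross <- function(n_chrom = 1, chrom_length_bp = 10e6,
                           n_sites_per_chrom = 2000, cM_per_Mb = 1,
                           n_individuals = 221,
                           qtl = "auto", qtl_pos_bp = 850000, h2 = 0.85,
                           n_environments = 3, n_replicates = 2, env_sd = 1,
                           k = 10, require_homozygous = FALSE,
                           mean_depth = 30, error_rate = 0.005,
                           seed = NULL) {
  with_seed(seed)
  map <- make_snp_map(n_chrom, chrom_length_bp, n_sites_per_chrom, cM_per_Mb)
  geno <- breed_f4(map, n_individuals)
  if (identical(qtl, "auto")) {
    s1 <- map$sites[map$sites$chrom == map$chromosomes$chrom[1], ]
    i <- which.min(abs(s1$pos - qtl_pos_bp))
    qtl <- qtl_spec(s1$chrom[i], s1$pos[i], h2 = h2)
  }
  pheno <- simulate_phenotypes(geno, qtl, n_environments, n_replicates,
                               env_sd = env_sd)
  rha <- if (!is.null(qtl) && require_homozygous) {
    list(chrom = qtl$chrom, pos = qtl$pos)
  } else {
    NULL
  }
  bulks <- select_bulks(pheno, geno, k = k, require_homozygous_at = rha)
  counts <- sequence_bulks(geno, bulks, mean_depth = mean_depth,
                           error_rate = error_rate)
  realized_h2 <- if (n_environments >= 2) broad_sense_h2(pheno)$h2 else NA_real_
  structure(list(map = map, geno = geno, pheno = pheno, bulks = bulks,
                 counts = counts, qtl = qtl, realized_h2 = realized_h2,
                 seed = seed),
            class = "bsa_sim")
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat(sprintf("<bsa_sim> %d individuals, %d sites on %d chromosome(s)\n",
              length(x$geno$individuals), nrow(x$map$sites),
              nrow(x$map$chromosomes)))
  if (!is.null(x$qtl)) {
    cat(sprintf("  causal QTL at %s:%s (H2 target %.2f, realized %.3f)\n",
                x$qtl$chrom, format(x$qtl$pos, big.mark = ","), x$qtl$h2,
                x$realized_h2))
  } else {
    cat("  null simulation (no QTL)\n")
  }
  invisible(x)
}

#' Run the QTL-seq scan: polarize, filter, index, window, CI, call
#'
#' Executes the analysis pipeline on an allele-depth table:
#' polarization to the high-parent allele, depth/quality filtering, per-SNP
#' SNP-index and delta(SNP-index), sliding-window averaging, null-model
#' confidence bounds conditional on read depth and design, and QTL-interval
#' calling.
#'
#' @param counts A `count_table` (from [sequence_bulks()],
#'   [read_counts_tsv()] or [read_counts_vcf()]).
#' @param chrom_lengths Named vector or tibble of chromosome lengths.
#' @param design A [null_design()] describing generation, bulk size and
#'   error rate (default F4, k = 10).
#' @param min_depth,min_quality Site filters (defaults 10 and 20).
#' @param window_bp,step_bp,min_snps Window scan parameters (defaults 5 Mb,
#'   10 kb, 3).
#' @param ci_depths Depths to tabulate null bounds at (default
#'   `c(10, 20, 30, 50, 100)`).
#' @param n_reps Null-simulation replicates per depth (default 10000).
#' @param level,hsb_min,lsb_max,min_run,abs_delta_min,use_index_criteria
#'   Interval-calling parameters (see [call_intervals()]).
#' @param ci Optionally a precomputed `ci_table` (skips simulation).
#' @param seed Seed for the null simulation.
#' @return A list of class `qtlseq_result`: `sites` (per-SNP indices),
#'   `windows` (with bounds), `intervals`, `ci`, and `log` (stage counts).
#' @export
run_qtlseq <- function(counts, chrom_lengths,
                       design = null_design("F4", k = 10),
                       min_depth = 10, min_quality = 20,
                       window_bp = 5e6, step_bp = 1e4, min_snps = 3,
                       ci_depths = c(10, 20, 30, 50, 100), n_reps = 10000,
                       level = 0.95, hsb_min = 0.9, lsb_max = 0.1,
                       min_run = 2, abs_delta_min = NULL,
                       use_index_criteria = TRUE,
                       ci = NULL, seed = NULL) {
  n_in <- nrow(counts)
  pol <- polarize(counts, min_parent_depth = min_depth)
  filt <- filter_sites(pol, min_depth = min_depth, min_quality = min_quality)
  sites <- compute_snp_index(filt)
  windows <- sliding_windows(sites, chrom_lengths, window_bp = window_bp,
                             step_bp = step_bp, min_snps = min_snps)
  if (is.null(ci)) {
    ci <- build_ci_table(design, depths = ci_depths, n_reps = n_reps,
                         seed = seed)
  }
  windows <- attach_ci(windows, sites, ci)
  intervals <- call_intervals(windows, level = level, hsb_min = hsb_min,
                              lsb_max = lsb_max, min_run = min_run,
                              abs_delta_min = abs_delta_min,
                              use_index_criteria = use_index_criteria)
  log <- tibble(
    stage = c("input", "polarized", "filtered", "windows", "intervals"),
    n = c(n_in, nrow(pol), nrow(sites), nrow(windows), nrow(intervals)),
    dropped = c(NA, n_in - nrow(pol), nrow(pol) - nrow(sites), NA, NA)
  )
  structure(list(sites = sites, windows = windows, intervals = intervals,
                 ci = ci, log = log,
                 params = list(min_depth = min_depth,
                               min_quality = min_quality,
                               window_bp = window_bp, step_bp = step_bp,
                               min_snps = min_snps, level = level,
                               hsb_min = hsb_min, lsb_max = lsb_max,
                               min_run = min_run)),
            class = "qtlseq_result")
}

#' @export
print.qtlseq_result <- function(x, ...) {
  cat("<qtlseq_result>\n")
  print(x$log)
  if (nrow(x$intervals)) {
    cat("called intervals:\n")
    print(x$intervals)
  } else {
    cat("no intervals called.\n")
  }
  invisible(x)
}

#' @rdname run_qtlseq
#' @param x A `qtlseq_result`.
#' @param ... Unused.
#' @method tidy qtlseq_result
#' @export
tidy.qtlseq_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$intervals))
}

#' @rdname run_qtlseq
#' @method glance qtlseq_result
#' @export
glance.qtlseq_result <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_windows = nrow(x$windows),
    n_intervals = nrow(x$intervals),
    max_abs_delta = if (nrow(x$windows)) {
      max(abs(x$windows$delta), na.rm = TRUE)
    } else {
      NA_real_
    },
    level = x$params$level
  )
}

#' Run the end-to-end pipeline from a configuration
#'
#' Thin orchestration layer intended for scripted use: simulate (optional),
#' scan, and write every intermediate table as TSV with a provenance header
#' (package version, config hash, seed). Configuration is a named list or a
#' YAML file with blocks `simulate` (arguments of [simulate_cross()]) and
#' `qtlseq` (arguments of [run_qtlseq()]), plus top-level `seed` and
#' `out_dir`.
#'
#' @param config A named list or path to a YAML file.
#' @param out_dir Output directory (overrides the config's).
#' @return The `qtlseq_result`, invisibly; files are written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("bsaqtl %s | config %s | seed %s",
                   as.character(utils::packageVersion("bsaqtl")),
                   rlang::hash(config), seed)

  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  sim <- do.call(simulate_cross, sim_args)
  write_counts_tsv(sim$counts, file.path(out_dir, "counts.tsv"),
                   comments = stamp)
  write_counts_vcf(sim$counts, file.path(out_dir, "counts.vcf"),
                   contig_lengths = stats::setNames(
                     sim$map$chromosomes$length_bp,
                     sim$map$chromosomes$chrom))
  write_geno_tsv(sim$geno, file.path(out_dir, "genotypes.tsv"))
  readr::write_tsv(as.data.frame(sim$pheno),
                   file.path(out_dir, "phenotypes.tsv"), progress = FALSE)

  q_args <- config$qtlseq %||% list()
  q_args$counts <- sim$counts
  q_args$chrom_lengths <- stats::setNames(sim$map$chromosomes$length_bp,
                                          sim$map$chromosomes$chrom)
  q_args$design <- q_args$design %||%
    null_design("F4", k = sim$bulks$k,
                error_rate = config$simulate$error_rate %||% 0.005)
  q_args$seed <- q_args$seed %||% seed
  res <- do.call(run_qtlseq, q_args)

  hdr_write <- function(df, path) {
    con <- file(path, "wb")
    writeLines(paste0("# ", stamp), con)
    readr::write_tsv(as.data.frame(df), con, progress = FALSE)
    close(con)
  }
  hdr_write(res$sites, file.path(out_dir, "snp_index.tsv"))
  hdr_write(res$windows, file.path(out_dir, "windows.tsv"))
  write_ci_tsv(res$ci, file.path(out_dir, "ci_table.tsv"))
  write_intervals(res$intervals,
                  bed_path = file.path(out_dir, "intervals.bed"),
                  tsv_path = file.path(out_dir, "intervals.tsv"))
  hdr_write(res$log, file.path(out_dir, "pipeline_log.tsv"))
  invisible(res)
}
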