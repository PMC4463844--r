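test_that("null delta matches exhaustive enumeration for tiny designs", {
  # RIL, k = 1, depth 1: delta in {-1, 0, 1} with probs {1/4, 1/2, 1/4}
  d_ril <- null_design("RIL", k = 1)
  ex <- exact_delta_dist(d_ril$geno_probs, 1, 1, 1)
  expect_equal(ex$values, c(-1, 0, 1))
  expect_equal(ex$probs, c(1, 2, 1) / 4)

  n <- 40000
  dl <- simulate_null_delta(d_ril, 1, 1, n, seed = 61)
  emp <- as.numeric(table(factor(dl, levels = c(-1, 0, 1)))) / n
  for (i in 1:3) {
    se <- sqrt(ex$probs[i] * (1 - ex$probs[i]) / n)
    expect_lt(abs(emp[i] - ex$probs[i]), 3 * se)
  }

  # all k = 1, depth <= 2 designs are enumerable: check every support atom
  for (gen in c("F2", "F4", "RIL")) {
    for (dep in 1:2) {
      des <- null_design(gen, k = 1)
      ex2 <- exact_delta_dist(des$geno_probs, 1, dep, dep)
      dl2 <- simulate_null_delta(des, dep, dep, 20000, seed = 62)
      for (i in seq_along(ex2$values)) {
        p_emp <- mean(abs(dl2 - ex2$values[i]) < 1e-9)
        se <- sqrt(ex2$probs[i] * (1 - ex2$probs[i]) / 20000) + 1e-12
        expect_lt(abs(p_emp - ex2$probs[i]), max(3 * se, 0.005))
      }
    }
  }
})

test_that("F4 bulk allele frequency has mean 1/2 and variance 7/(32k)", {
  des <- null_design("F4", k = 10)
  set.seed(63)
  p <- bsaqtl:::.bulk_freqs(des, 100000)
  expect_lt(abs(mean(p) - 0.5), 3 * sd(p) / sqrt(length(p)))
  v_exact <- 7 / (32 * 10)  # p(1-p) (1+F) / (2k) with F = 3/4
  # variance of the 10-fold mean of {0, 1/2, 1} draws under the 7:2:7 law
  expect_lt(abs(var(p) - v_exact) / v_exact, 0.05)
  # agreement with the enumerated convolution
  cnt <- bulk_allele_count_dist(des$geno_probs, 10)
  vals <- (0:20) / 20
  expect_equal(sum(cnt * vals), 0.5)
  expect_equal(sum(cnt * vals^2) - 0.25, v_exact)
})

test_that("null delta distribution is symmetric around zero", {
  for (gen in c("F2", "F4", "RIL")) {
    des <- null_design(gen, k = 10)
    dl <- simulate_null_delta(des, 30, 30, 10000, seed = 64)
    expect_lt(abs(mean(dl)), 3 * sd(dl) / sqrt(length(dl)))
    skew <- mean((dl - mean(dl))^3) / sd(dl)^3
    expect_lt(abs(skew), 0.1)
  }
})

test_that("CI tables nest across levels and shrink with depth", {
  des <- null_design("F4", k = 10)
  ci <- build_ci_table(des, depths = c(10, 20, 50, 100), n_reps = 10000,
                       seed = 65)
  expect_true(all(ci$lo99 <= ci$lo95))
  expect_true(all(ci$hi99 >= ci$hi95))
  expect_true(all(ci$hi95 >= 0 & ci$lo95 <= 0))
  expect_true(all(ci$lo95 >= -1 & ci$hi99 <= 1))

  width95 <- ci$hi95 - ci$lo95
  width99 <- ci$hi99 - ci$lo99
  expect_lte(sum(diff(width95) > 0), 1)  # allow one Monte-Carlo violation
  expect_lte(sum(diff(width99) > 0), 1)

  expect_warning(build_ci_table(des, depths = 10, n_reps = 500, seed = 1),
                 "unstable")
  expect_error(build_ci_table(des, depths = numeric(0)), "non-empty")
})

test_that("fresh null data falls outside the bounds at the enumerated rate", {
  # delta lives on a lattice (multiples of 1/depth), so the achieved
  # exceedance of empirical-quantile bounds can differ from the nominal
  # rate by up to the probability mass of the lattice atoms at the bounds,
  # plus the Monte-Carlo error of estimating the quantiles themselves
  des <- null_design("F4", k = 10)
  n_ci <- 20000
  ci <- build_ci_table(des, depths = c(10, 30, 100), n_reps = n_ci,
                       seed = 66)
  n <- 20000
  eps <- 1e-9
  atom_near <- function(dist, x) dist$probs[which.min(abs(dist$values - x))]
  for (dep in c(10, 30, 100)) {
    fresh <- simulate_null_delta(des, dep, dep, n, seed = 660 + dep)
    row <- ci[ci$depth == dep, ]
    ex <- exact_delta_dist(des$geno_probs, 10, dep, dep)
    for (lev in c(95, 99)) {
      alpha <- 1 - lev / 100
      lo <- row[[sprintf("lo%d", lev)]]
      hi <- row[[sprintf("hi%d", lev)]]
      p_exact <- sum(ex$probs[ex$values < lo - eps | ex$values > hi + eps])
      p_emp <- mean(fresh < lo - eps | fresh > hi + eps)
      se <- sqrt(p_exact * (1 - p_exact) / n)
      # the simulator reproduces the enumerated law at the fitted bounds
      expect_lt(abs(p_emp - p_exact), 3 * se + 1e-6)
      # achieved coverage is nominal up to discreteness + quantile MC error
      band <- atom_near(ex, lo) + atom_near(ex, hi) +
        6 * sqrt(alpha * (1 - alpha) / n_ci)
      expect_lt(abs(p_exact - alpha), band + 1e-6)
    }
  }
})

test_that("window bounds are depth-lookup averages of per-SNP bounds", {
  des <- null_design("F4", k = 10)
  ci <- build_ci_table(des, depths = c(10, 100), n_reps = 5000, seed = 67)

  # all SNPs at one tabulated depth: window bound equals that row
  recs <- tibble::tibble(chrom = "c", pos = c(10, 20, 30),
                         lsb_high = c(1, 2, 3), lsb_depth = 10,
                         hsb_high = c(9, 8, 7), hsb_depth = 10) |>
    compute_snp_index()
  w <- sliding_windows(recs, c(c = 40), window_bp = 40, step_bp = 40,
                       min_snps = 1)
  wb <- attach_ci(w, recs, ci)
  expect_equal(wb$lo95, ci$lo95[ci$depth == 10])
  expect_equal(wb$hi99, ci$hi99[ci$depth == 10])

  # mixed depths 10 and 100 in equal numbers: midpoint of the two rows
  recs2 <- tibble::tibble(chrom = "c", pos = c(10, 20),
                          lsb_high = c(1, 10), lsb_depth = c(10, 100),
                          hsb_high = c(9, 90), hsb_depth = c(10, 100)) |>
    compute_snp_index()
  w2 <- attach_ci(sliding_windows(recs2, c(c = 40), window_bp = 40,
                                  step_bp = 40, min_snps = 1),
                  recs2, ci)
  expect_equal(w2$lo95, mean(ci$lo95))
  expect_equal(w2$hi95, mean(ci$hi95))

  # off-table depths clamp to the nearest tabulated depth; brute force
  recs3 <- tibble::tibble(chrom = "c", pos = c(10, 20, 30),
                          lsb_high = c(1, 5, 9), lsb_depth = c(12, 60, 90),
                          hsb_high = c(9, 40, 80), hsb_depth = c(14, 55, 95)) |>
    compute_snp_index()
  w3 <- attach_ci(sliding_windows(recs3, c(c = 40), window_bp = 40,
                                  step_bp = 40, min_snps = 1),
                  recs3, ci)
  min_dep <- pmin(recs3$lsb_depth, recs3$hsb_depth)
  near <- vapply(min_dep, function(d) which.min(abs(ci$depth - d)), 1L)
  expect_equal(w3$lo95, mean(ci$lo95[near]))

  # windows without SNPs carry no bounds
  w4 <- attach_ci(sliding_windows(recs3, c(c = 200), window_bp = 50,
                                  step_bp = 50, min_snps = 1),
                  recs3, ci)
  expect_true(all(is.na(w4$lo95[w4$n_snps == 0])))
})
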