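test_that("snp maps are sorted, bounded and deterministic", {
  m <- make_snp_map(n_chrom = 8, chrom_length_bp = 1e7,
                    n_sites_per_chrom = 1000, seed = 1)
  expect_equal(nrow(m$chromosomes), 8)
  by_chrom <- split(m$sites$pos, m$sites$chrom)
  expect_true(all(vapply(by_chrom, function(p) all(diff(p) > 0), TRUE)))
  expect_true(all(m$sites$pos >= 1 & m$sites$pos <= 1e7))
  expect_true(all(m$sites$low_allele != m$sites$high_allele))

  m2 <- make_snp_map(n_chrom = 8, chrom_length_bp = 1e7,
                     n_sites_per_chrom = 1000, seed = 1)
  expect_identical(m, m2)

  empty <- make_snp_map(n_chrom = 1, chrom_length_bp = 1e7,
                        n_sites_per_chrom = 0, seed = 5)
  expect_equal(nrow(empty$sites), 0)
  expect_error(make_snp_map(chrom_length_bp = -5), "chrom_length_bp")
})

test_that("F4 genotype frequencies match the exact selfing Markov chain", {
  f4 <- selfing_chain_probs(3)
  expect_equal(unname(f4), c(7, 2, 7) / 16)  # the chain itself

  # no recombination: whole-chromosome genotypes, 7:2:7 law
  map <- make_snp_map(n_chrom = 1, chrom_length_bp = 1e6,
                      n_sites_per_chrom = 20, cM_per_Mb = 0, seed = 2)
  geno <- breed_f4(map, n_individuals = 2000, seed = 3)
  per_ind_unique <- apply(geno$dosage, 1, function(x) length(unique(x)))
  expect_true(all(per_ind_unique == 1))  # constant within chromosome

  het <- mean(geno$dosage[, 1] == 1L)
  se <- sqrt(f4[["LH"]] * (1 - f4[["LH"]]) / 2000)
  expect_lt(abs(het - f4[["LH"]]), 3 * se)
  hom_hi <- mean(geno$dosage[, 1] == 2L)
  expect_lt(abs(hom_hi - f4[["HH"]]), 3 * sqrt(f4[["HH"]] * (1 - f4[["HH"]]) / 2000))
})

test_that("F4 heterozygosity with recombination stays at 1/8 over >=1e4 draws", {
  # one site per chromosome so the individual-site draws are independent
  # and the binomial standard error is exact
  map <- make_snp_map(n_chrom = 100, chrom_length_bp = 5e6,
                      n_sites_per_chrom = 1, cM_per_Mb = 2, seed = 4)
  geno <- breed_f4(map, n_individuals = 120, seed = 5)
  draws <- length(geno$dosage)
  expect_gte(draws, 1e4)
  het <- mean(geno$dosage == 1L)
  se <- sqrt(0.125 * 0.875 / draws)
  expect_lt(abs(het - 0.125), 3 * se)
})

test_that("breeding respects population size and determinism", {
  map <- make_snp_map(n_chrom = 1, chrom_length_bp = 1e6,
                      n_sites_per_chrom = 10, seed = 1)
  geno <- breed_f4(map, n_individuals = 221, seed = 9)
  expect_equal(length(geno$individuals), 221)
  expect_identical(geno$dosage,
                   breed_f4(map, n_individuals = 221, seed = 9)$dosage)
  expect_error(breed_f4(map, n_individuals = 0), "n_individuals")
  tb <- tibble::as_tibble(geno)
  expect_setequal(unique(tb$genotype), c("LL", "LH", "HH"))
})

test_that("fully heritable phenotypes hit the parental means exactly", {
  sim_map <- make_snp_map(1, 1e6, 50, cM_per_Mb = 0, seed = 11)
  geno <- breed_f4(sim_map, 100, seed = 12)
  q <- qtl_spec(sim_map$sites$chrom[25], sim_map$sites$pos[25], h2 = 1)
  ph <- simulate_phenotypes(geno, q, n_environments = 3, n_replicates = 2,
                            seed = 13)
  im <- individual_means(ph)
  dos <- geno$dosage[im$individual, 25]
  expect_equal(unname(im$mean_value[dos == 0]),
               rep(8.9, sum(dos == 0)))
  expect_equal(unname(im$mean_value[dos == 2]),
               rep(30.1, sum(dos == 2)))
  expect_equal(unname(im$mean_value[dos == 1]),
               rep(19.5, sum(dos == 1)))
})

test_that("zero heritability is rejected and monomorphic QTLs carry no signal", {
  expect_error(qtl_spec("chr1", 100, h2 = 0), "h2")

  sim_map <- make_snp_map(1, 1e6, 30, cM_per_Mb = 0, seed = 14)
  geno <- breed_f4(sim_map, 120, seed = 15)
  geno$dosage[, 10] <- 2L  # force the causal site monomorphic
  q <- qtl_spec(sim_map$sites$chrom[10], sim_map$sites$pos[10], h2 = 0.9)
  ph <- simulate_phenotypes(geno, q, seed = 16)
  scan <- single_marker_scan(geno, ph)
  expect_true(scan$monomorphic[10])
  expect_true(is.na(scan$r_squared[10]))
})

test_that("bulk selection takes the phenotypic extremes with stable ties", {
  sim <- toy_sim(seed = 21)
  # full penetrance: every HSB member is HH, every LSB member LL at the QTL
  ci <- which(sim$map$sites$pos == sim$qtl$pos)
  expect_true(all(sim$geno$dosage[sim$bulks$hsb, ci] == 2L))
  expect_true(all(sim$geno$dosage[sim$bulks$lsb, ci] == 0L))
  expect_length(intersect(sim$bulks$lsb, sim$bulks$hsb), 0)

  # brute-force check of the ranking
  im <- individual_means(sim$pheno)
  ord <- im$individual[order(im$mean_value, im$individual)]
  expect_setequal(sim$bulks$lsb, head(ord, 10))
  expect_setequal(sim$bulks$hsb, tail(ord, 10))

  # k = n/2 partitions everyone
  b2 <- select_bulks(sim$pheno, sim$geno, k = 40)
  expect_setequal(c(b2$lsb, b2$hsb), sim$geno$individuals)

  expect_error(select_bulks(sim$pheno, sim$geno, k = 41), "exceeds")
})

test_that("homozygosity screening skips heterozygotes while filling bulks", {
  sim <- simulate_cross(n_chrom = 1, chrom_length_bp = 2e6,
                        n_sites_per_chrom = 100, n_individuals = 80,
                        h2 = 0.5, require_homozygous = TRUE, seed = 22)
  ci <- which(sim$map$sites$pos == sim$qtl$pos)
  expect_true(all(sim$geno$dosage[c(sim$bulks$lsb, sim$bulks$hsb), ci] != 1L))
})

test_that("read sampling conserves depth and matches binomial expectations", {
  sim <- toy_sim(seed = 31)
  cnt <- sim$counts
  expect_true(all(cnt$lsb_ref + cnt$lsb_alt >= 1))
  expect_true(all(cnt$hsb_ref + cnt$hsb_alt >= 1))
  expect_true(all(cnt$lp_ref + cnt$lp_alt >= 1))

  # all-HH bulk, no error: every read carries the high allele
  map <- make_snp_map(1, 1e6, 200, cM_per_Mb = 0, seed = 32)
  geno <- breed_f4(map, 40, seed = 33)
  geno$dosage[1:10, ] <- 2L
  geno$dosage[11:20, ] <- 0L
  bulks <- structure(list(lsb = geno$individuals[11:20],
                          hsb = geno$individuals[1:10], k = 10L),
                     class = "bulk_sets")
  cnt0 <- sequence_bulks(geno, bulks, mean_depth = 20, error_rate = 0,
                         seed = 34)
  hsb_high <- ifelse(map$sites$high_is_ref, cnt0$hsb_ref, cnt0$hsb_alt)
  expect_true(all(hsb_high == cnt0$hsb_ref + cnt0$hsb_alt))
  lsb_high <- ifelse(map$sites$high_is_ref, cnt0$lsb_ref, cnt0$lsb_alt)
  expect_true(all(lsb_high == 0))

  # 5 HH + 5 LL bulk: Monte-Carlo mean high fraction within 3 SE of 0.5
  map2 <- make_snp_map(1, 1e7, 10000, cM_per_Mb = 0, seed = 35)
  geno2 <- breed_f4(map2, 20, seed = 36)
  geno2$dosage[1:5, ] <- 2L
  geno2$dosage[6:10, ] <- 0L
  geno2$dosage[11:20, ] <- 0L
  bulks2 <- structure(list(lsb = geno2$individuals[11:20],
                           hsb = geno2$individuals[1:10], k = 10L),
                      class = "bulk_sets")
  cnt2 <- sequence_bulks(geno2, bulks2, mean_depth = 20, error_rate = 0,
                         seed = 37)
  frac <- ifelse(map2$sites$high_is_ref, cnt2$hsb_ref, cnt2$hsb_alt) /
    (cnt2$hsb_ref + cnt2$hsb_alt)
  # per-site variance of the read fraction at p = 0.5, depth ~20
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)

  expect_error(sequence_bulks(geno2, bulks2, mean_depth = 20,
                              error_rate = 0.7), "error_rate")
})

test_that("the generator is deterministic end to end", {
  a <- toy_sim(seed = 77)
  b <- toy_sim(seed = 77)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$pheno$value, b$pheno$value)
  expect_identical(a$bulks$hsb, b$bulks$hsb)
  expect_identical(as.data.frame(a$counts), as.data.frame(b$counts))
})
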