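make_counts <- function(...) {
  rows <- list(...)
  df <- tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(as.list(r), stringsAsFactors = FALSE)
  })))
  for (cc in setdiff(names(df), c("chrom", "ref", "alt"))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  class(df) <- c("count_table", class(df))
  df
}

row1 <- c(chrom = "chr1", pos = 100, ref = "A", alt = "G", qual = 60,
          lsb_ref = 18, lsb_alt = 2, hsb_ref = 1, hsb_alt = 19,
          lp_ref = 20, lp_alt = 0, hp_ref = 0, hp_alt = 20)

test_that("TSV counts round-trip exactly", {
  sim <- toy_sim(seed = 41)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sim$counts, f)
  back <- read_counts_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$counts))

  # header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste0("#", paste(names(sim$counts), collapse = "\t")), f2)
  expect_equal(nrow(read_counts_tsv(f2)), 0)

  # negative depth rejected with its line number
  f3 <- withr::local_tempfile(fileext = ".tsv")
  x <- sim$counts[1:3, ]
  x$lsb_ref[2] <- -4
  write_counts_tsv(x, f3)
  expect_error(read_counts_tsv(f3), "line 3")
})

test_that("VCF counts round-trip and match the TSV reader", {
  sim <- toy_sim(seed = 42)
  fv <- withr::local_tempfile(fileext = ".vcf")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_counts_vcf(sim$counts, fv)
  write_counts_tsv(sim$counts, ft)
  from_vcf <- read_counts_vcf(fv)
  from_tsv <- read_counts_tsv(ft)
  expect_equal(as.data.frame(from_vcf), as.data.frame(from_tsv),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(from_vcf, "skipped"), 0L)
})

test_that("multi-allelic and indel VCF lines are skipped and counted", {
  f <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "LSB", "HSB", "LOW_PARENT",
                   "HIGH_PARENT"), collapse = "\t"))
  body <- c(
    "chr1\t100\t.\tA\tG\t60\tPASS\t.\tAD\t3,7\t1,9\t10,0\t0,10",
    "chr1\t200\t.\tA\tG,T,C\t60\tPASS\t.\tAD\t3,7,0,0\t1,9,0,0\t10,0,0,0\t0,10,0,0",
    "chr1\t300\t.\tAT\tA\t60\tPASS\t.\tAD\t3,7\t1,9\t10,0\t0,10",
    "chr1\t400\t.\tC\tT\t60\tPASS\t.\tAD\t5,5\t2,8\t12,0\t0,12")
  writeLines(c(hdr, body), f)
  x <- read_counts_vcf(f)
  expect_equal(nrow(x), 2)
  expect_equal(attr(x, "skipped"), 2L)
  expect_equal(x$lsb_ref, c(3, 5))
  expect_equal(x$hsb_alt, c(9, 8))

  expect_error(read_counts_vcf(f, sample_names = c(
    lsb = "NOPE", hsb = "HSB", low_parent = "LOW_PARENT",
    high_parent = "HIGH_PARENT")), "NOPE")
})

test_that("empty VCF body gives an empty table", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "LSB", "HSB",
                       "LOW_PARENT", "HIGH_PARENT"), collapse = "\t")), f)
  expect_equal(nrow(suppressWarnings(read_counts_vcf(f))), 0)
})

test_that("polarization keeps only fixed parental differences", {
  # low parent fixed REF, high parent fixed ALT: high allele is ALT
  x <- make_counts(row1)
  p <- polarize(x)
  expect_equal(nrow(p), 1)
  expect_false(p$high_is_ref)
  expect_equal(p$hsb_high, 19)
  expect_equal(p$hsb_depth, 20)

  # mirrored orientation: reference carries the high allele
  y <- make_counts(row1)
  y[, c("lp_ref", "lp_alt")] <- list(0, 20)
  y[, c("hp_ref", "hp_alt")] <- list(20, 0)
  y[, c("hsb_ref", "hsb_alt")] <- list(19, 1)
  y[, c("lsb_ref", "lsb_alt")] <- list(2, 18)
  q <- polarize(y)
  expect_true(q$high_is_ref)
  expect_equal(q$hsb_high, 19)
  # swap consistency: SNP-index identical in both orientations
  expect_equal(compute_snp_index(q)$hsb_index, compute_snp_index(p)$hsb_index)
  expect_equal(compute_snp_index(q)$lsb_index, compute_snp_index(p)$lsb_index)

  # both parents fixed for REF: dropped
  z <- make_counts(row1)
  z[, c("hp_ref", "hp_alt")] <- list(20, 0)
  expect_equal(nrow(polarize(z)), 0)
  expect_equal(attr(polarize(z), "n_dropped"), 1L)

  # shallow parent: not confidently fixed, dropped
  w <- make_counts(row1)
  w[, c("hp_ref", "hp_alt")] <- list(0, 5)
  expect_equal(nrow(polarize(w, min_parent_depth = 10)), 0)
})

test_that("site filters apply boundary-inclusive thresholds per bulk", {
  s <- tibble::tibble(
    chrom = "chr1", pos = c(1, 2, 3, 4), qual = c(20, 30, 19, 25),
    high_is_ref = TRUE,
    lsb_high = c(5, 4, 15, 20), lsb_depth = c(10, 9, 30, 30),
    hsb_high = c(5, 15, 15, 20), hsb_depth = c(10, 30, 30, 30)
  )
  out <- filter_sites(s, min_depth = 10, min_quality = 20)
  expect_equal(out$pos, c(1, 4))   # (10,10,q20) kept; (9,30) and q19 removed

  # idempotence and subset property
  out2 <- filter_sites(out, min_depth = 10, min_quality = 20)
  expect_equal(as.data.frame(out2)[names(s)], as.data.frame(out)[names(s)])
  expect_true(all(out$pos %in% s$pos))
})

test_that("polarization is involution-safe on mirrored simulated data", {
  sim <- toy_sim(seed = 43)
  # mirror the file: swap REF/ALT labels and all ref/alt count pairs
  m <- sim$counts
  swap <- function(df, a, b) {
    tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df
  }
  m <- swap(m, "ref", "alt")
  for (smp in c("lsb", "hsb", "lp", "hp")) {
    m <- swap(m, paste0(smp, "_ref"), paste0(smp, "_alt"))
  }
  i1 <- compute_snp_index(filter_sites(polarize(sim$counts)))
  i2 <- compute_snp_index(filter_sites(polarize(m)))
  expect_equal(i1$hsb_index, i2$hsb_index)
  expect_equal(i1$delta, i2$delta)
})
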