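# SNP layer: PLINK I/O, QC and the single-marker allelic test.

test_that("PLINK round-trip reproduces genotypes, SNP order and phenotypes", {
  cfg <- simulation_config(n_cases = 7, n_controls = 9, n_snps = 23,
                           missing_rate = 0.1, seed = 42)
  ds <- simulate_dataset(cfg)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(ds, prefix)
  back <- read_plink(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                     paste0(prefix, ".fam"))
  expect_identical(unname(back$genotypes), unname(ds$genotypes))
  expect_identical(back$snps$snp_id, ds$snps$snp_id)
  expect_identical(back$snps$pos, ds$snps$pos)
  expect_identical(as.character(back$phenotype), as.character(ds$phenotype))
  expect_identical(back$sample_ids, ds$sample_ids)
})

test_that("malformed bed files are rejected", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_cases = 3, n_controls = 3, n_snps = 4, seed = 1)
  ds <- simulate_dataset(cfg)
  write_plink(ds, file.path(dir, "ok"))

  bad <- file.path(dir, "bad.bed")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xff)), bad)
  expect_error(read_plink(bad, file.path(dir, "ok.bim"),
                          file.path(dir, "ok.fam")),
               "magic")

  # truncate the valid bed -> dimension mismatch
  raw <- readBin(file.path(dir, "ok.bed"), "raw",
                 file.size(file.path(dir, "ok.bed")))
  writeBin(raw[-length(raw)], file.path(dir, "trunc.bed"))
  expect_error(read_plink(file.path(dir, "trunc.bed"),
                          file.path(dir, "ok.bim"),
                          file.path(dir, "ok.fam")),
               "inconsistent")
})

test_that("hand-encoded bed decodes per the 2-bit SNP-major layout", {
  dir <- withr::local_tempdir()
  # 3 samples, 2 SNPs, every genotype homozygous for the major (A2) allele:
  # 2-bit code 11 for each sample, padding slots also 11 -> byte 0xff
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xff, 0xff)),
           file.path(dir, "hand.bed"))
  writeLines(c("1\tsA\t0\t100\tA\tB", "1\tsB\t0\t200\tA\tB"),
             file.path(dir, "hand.bim"))
  writeLines(c("f1 i1 0 0 0 2", "f2 i2 0 0 0 1", "f3 i3 0 0 0 1"),
             file.path(dir, "hand.fam"))
  ds <- read_plink(file.path(dir, "hand.bed"), file.path(dir, "hand.bim"),
                   file.path(dir, "hand.fam"))
  expect_identical(unname(ds$genotypes),
                   matrix(0L, nrow = 3, ncol = 2))
  expect_identical(as.character(ds$phenotype),
                   c("case", "control", "control"))

  # mixed byte: codes 00 (dosage 2), 10 (1), 01 (NA) for samples 1..3
  # byte = 0 + 4*2 + 16*1 + 64*1 (pad) = 0x58
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x58)), file.path(dir, "mix.bed"))
  writeLines("1\tsA\t0\t100\tA\tB", file.path(dir, "mix.bim"))
  ds2 <- read_plink(file.path(dir, "mix.bed"), file.path(dir, "mix.bim"),
                    file.path(dir, "hand.fam"))
  expect_identical(unname(ds2$genotypes),
                   matrix(c(2L, 1L, NA_integer_), ncol = 1))
})

test_that("samples with missing phenotype are dropped with a warning", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_cases = 2, n_controls = 2, n_snps = 3, seed = 5)
  ds <- simulate_dataset(cfg)
  write_plink(ds, file.path(dir, "p"))
  fam <- readLines(file.path(dir, "p.fam"))
  fam[2] <- sub("\t2$", "\t-9", fam[2])
  writeLines(fam, file.path(dir, "p.fam"))
  expect_warning(
    back <- read_plink(file.path(dir, "p.bed"), file.path(dir, "p.bim"),
                       file.path(dir, "p.fam")),
    "missing phenotype")
  expect_identical(length(back$sample_ids), 3L)

  fam[3] <- sub("\t[12]$", "\t7", fam[3])
  writeLines(fam, file.path(dir, "p.fam"))
  expect_error(read_plink(file.path(dir, "p.bed"), file.path(dir, "p.bim"),
                          file.path(dir, "p.fam")),
               "phenotype codes")
})

test_that("QC removes low-MAF, high-missingness SNPs and nothing else", {
  set.seed(10)
  n <- 100  # 50 cases, 50 controls
  pheno <- rep(c("case", "control"), each = 50)
  good <- replicate(23, rbinom(n, 2, 0.3))
  low_maf <- rbinom(n, 2, 0.03)           # MAF < 0.05 -> removed
  gappy <- rbinom(n, 2, 0.3)
  gappy[1:6] <- NA   # 6% of calls missing, spread over 6 samples (4% each)
  geno <- cbind(good, low_maf, gappy)
  ds <- make_dataset(geno, pheno)
  res <- apply_qc_filters(ds)
  expect_false("s24" %in% res$dataset$snps$snp_id)  # low MAF
  expect_false("s25" %in% res$dataset$snps$snp_id)  # 6% missing
  expect_equal(res$report$removed_by_maf, 1)
  expect_equal(res$report$removed_by_missingness, 1)
  expect_equal(res$report$n_snps_out,
               res$report$n_snps_in - res$report$removed_by_missingness -
                 res$report$removed_by_maf - res$report$removed_by_hwe)

  # clean dataset: returned unchanged with all-zero removals
  ds2 <- make_dataset(good, pheno)
  res2 <- apply_qc_filters(ds2)
  expect_identical(res2$dataset$genotypes, ds2$genotypes)
  expect_equal(res2$report$removed_by_missingness +
                 res2$report$removed_by_maf + res2$report$removed_by_hwe +
                 res2$report$removed_samples_by_missingness, 0)
})

test_that("QC is monotone in the MAF threshold", {
  cfg <- simulation_config(n_cases = 40, n_controls = 40, n_snps = 60,
                           maf_range = c(0.02, 0.5), seed = 3)
  ds <- simulate_dataset(cfg)
  survivors <- vapply(c(0, 0.02, 0.05, 0.1, 0.2), function(m)
    apply_qc_filters(ds, min_maf = m)$report$n_snps_out, numeric(1))
  expect_true(all(diff(survivors) <= 0))
})

test_that("HWE exact test matches a brute-force enumeration oracle", {
  # brute force: enumerate all het counts with the observed allele counts,
  # binomial-coefficient probabilities, sum those <= observed
  brute <- function(n_AA, n_Aa, n_aa) {
    n <- n_AA + n_Aa + n_aa
    n_a <- 2 * n_aa + n_Aa
    hets <- seq(min(n_a, 2 * n - n_a) %% 2, min(n_a, 2 * n - n_a), by = 2)
    pr <- vapply(hets, function(h) {
      naa <- (n_a - h) / 2
      nAA <- n - naa - h
      exp(lfactorial(n) - lfactorial(nAA) - lfactorial(h) -
            lfactorial(naa) + h * log(2) +
            lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n))
    }, numeric(1))
    obs <- pr[hets == n_Aa]
    min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
  }
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_equal(hwe_exact_test(0, 0, 10), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(50, 0, 50), brute(50, 0, 50))
  set.seed(77)
  for (i in 1:25) {
    cnt <- as.vector(stats::rmultinom(1, size = sample(10:80, 1),
                                      prob = c(0.3, 0.45, 0.25)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 brute(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "undefined")
})

test_that("allelic test reproduces the hand-evaluated 2x2 chi-square", {
  ds <- dataset_from_allele_table(60, 40, 40, 60)
  res <- allelic_association(ds)
  expect_equal(res$chi_square, 8, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(8, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical allele frequencies -> null table
  ds0 <- dataset_from_allele_table(50, 50, 50, 50)
  res0 <- allelic_association(ds0)
  expect_equal(res0$chi_square, 0)
  expect_equal(res0$p_value, 1)

  # monomorphic SNP -> p = 1 by convention
  dsm <- make_dataset(matrix(0L, nrow = 8, ncol = 1),
                      rep(c("case", "control"), 4))
  expect_equal(allelic_association(dsm)$p_value, 1)
})

test_that("allelic p-values match chisq.test on 100 random allele tables", {
  set.seed(2024)
  for (i in 1:100) {
    maf <- runif(1, 0.1, 0.5)
    geno <- matrix(rbinom(60, 2, maf), ncol = 1)
    pheno <- rep(c("case", "control"), each = 30)
    ds <- make_dataset(geno, pheno)
    a1 <- c(sum(geno[1:30]), sum(geno[31:60]))
    tab <- rbind(a1, 60 - a1)
    res <- allelic_association(ds)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(res$p_value, 1)
    } else {
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
      expect_equal(res$chi_square, unname(ref$statistic), tolerance = 1e-10)
    }
  }
})

test_that("per-SNP p-values are invariant under sample shuffling", {
  cfg <- simulation_config(n_cases = 25, n_controls = 25, n_snps = 30,
                           missing_rate = 0.05, seed = 8)
  ds <- simulate_dataset(cfg)
  p1 <- allelic_association(ds)$p_value
  set.seed(99)
  perm <- sample(length(ds$sample_ids))
  ds2 <- subset_dataset(ds, samples = perm)
  p2 <- allelic_association(ds2)$p_value
  expect_identical(p1, p2)
})
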