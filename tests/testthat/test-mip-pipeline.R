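# Stage orchestration, best lists, consistency and attribution.

fake_result <- function(pathway, p, n_snps = 5, family = "simple",
                        tier = "none") {
  set_ <- mipgwas:::.new_pathway_set(pathway, family, tier,
                                     paste0("g", seq_len(max(1, n_snps %/% 2))),
                                     sprintf("%s_%s_%s_s%02d", pathway,
                                             family, tier, seq_len(n_snps)))
  r <- round(p * 501) - 1
  mipgwas:::.new_set_result(set_, statistic = -log(p), n_perm = 500,
                            r = max(r, 0), p_value = p, method = "sampled")
}

fake_stage <- function(best_entries, threshold = NA_real_) {
  base::structure(list(exclusion_threshold = threshold, n_snps_used = 100L,
                       results = unname(best_entries),
                       best = best_entries, alpha = 0.05,
                       table = set_results_table(unname(best_entries))),
                  class = "stage_result")
}

test_that("best_list keeps the minimal-p set per pathway, only if <= 0.05", {
  res <- list(fake_result("A", 0.2), fake_result("A", 0.01),
              fake_result("A", 0.04), fake_result("B", 0.2),
              fake_result("B", 0.6))
  bl <- best_list(res)
  expect_identical(names(bl), "A")
  expect_equal(bl[["A"]]$p_value, 0.01)

  # the 0.05 boundary is inclusive
  expect_length(best_list(list(fake_result("C", 0.05))), 1)
  expect_length(best_list(list(fake_result("C", 0.0500001))), 0)

  # ties at minimal p: larger SNP count wins, then family precedence
  tie <- list(fake_result("D", 0.02, n_snps = 4, family = "interaction",
                          tier = "low"),
              fake_result("D", 0.02, n_snps = 9,
                          family = "characteristic"))
  expect_identical(best_list(tie)[["D"]]$family, "characteristic")
  tie2 <- list(fake_result("D", 0.02, n_snps = 6, family = "interaction",
                           tier = "low"),
               fake_result("D", 0.02, n_snps = 6, family = "simple"))
  expect_identical(best_list(tie2)[["D"]]$family, "simple")
})

test_that("stage exclusion removes exactly the SNPs below threshold", {
  study <- small_study(seed = 41, effect_pathway = "pw_001",
                       odds_ratio = 2.0)
  ds <- study$dataset
  assoc <- allelic_association(ds)
  thr <- sort(assoc$p_value)[4]  # cut inside the observed distribution
  st <- run_stage(ds, study$structure, exclusion_threshold = thr,
                  n_perm = 50, seed = 1)
  expect_identical(st$n_snps_used, sum(assoc$p_value >= thr))
  st_all <- run_stage(ds, study$structure, n_perm = 50, seed = 1)
  expect_identical(st_all$n_snps_used, nrow(ds$snps))
  expect_true(is.na(st_all$exclusion_threshold))
  expect_error(run_stage(ds, study$structure, exclusion_threshold = 2),
               "exclusion_threshold")
})

test_that("stage SNP universes shrink as thresholds tighten", {
  study <- small_study(seed = 55, effect_pathway = "pw_002",
                       odds_ratio = 1.8)
  # a larger exclusion threshold removes more SNPs: ordering stages by
  # increasing threshold, the SNP universe is non-increasing
  rep_ <- run_mip(study$dataset, study$structure,
                  thresholds = c(NA, 0.001, 0.01, 0.05), n_perm = 50,
                  seed = 9)
  used <- vapply(rep_$stages, `[[`, integer(1), "n_snps_used")
  expect_true(all(diff(used) <= 0))
})

test_that("consistency requires p <= alpha in every stage", {
  s1 <- fake_stage(list(A = fake_result("A", 0.01),
                        B = fake_result("B", 0.04)))
  s2 <- fake_stage(list(A = fake_result("A", 0.02)), threshold = 1e-3)
  out <- consistent_pathways(list(s1, s2))
  expect_identical(out$pathway_id, "A")
  expect_equal(out$p_all, 0.01)
  expect_equal(out[["p_1e-03"]], 0.02)

  # pathway significant everywhere but one stage at 0.06 -> excluded there
  s3 <- fake_stage(list(B = fake_result("B", 0.04)), threshold = 1e-4)
  expect_identical(nrow(consistent_pathways(list(s1, s2, s3))), 0L)

  # an empty stage best list empties the intersection
  s4 <- fake_stage(list(), threshold = 1e-5)
  expect_identical(nrow(consistent_pathways(list(s1, s4))), 0L)
  expect_error(consistent_pathways(list(s1)), "at least two")

  # invariant under stage order permutation
  a <- consistent_pathways(list(s1, s2))
  b <- consistent_pathways(list(s2, s1))
  expect_identical(a$pathway_id, b$pathway_id)
})

test_that("method attribution reports per-family fractions that sum to 1", {
  # 24 consistent winners, 11 of interaction family
  entries <- c(
    lapply(1:11, function(i)
      fake_result(sprintf("I%02d", i), 0.01, family = "interaction",
                  tier = "low")),
    lapply(1:9, function(i) fake_result(sprintf("S%02d", i), 0.01)),
    lapply(1:4, function(i)
      fake_result(sprintf("C%02d", i), 0.01, family = "characteristic")))
  names(entries) <- vapply(entries, `[[`, character(1), "pathway_id")
  stages <- list(fake_stage(entries), fake_stage(entries, 1e-3))
  att <- method_attribution(stages)
  expect_equal(att$consistent[["interaction_share"]], 11 / 24,
               tolerance = 1e-12)
  expect_equal(round(100 * att$consistent[["interaction_share"]], 2),
               45.83)
  expect_equal(sum(att$per_stage[1, c("simple", "characteristic",
                                      "interaction",
                                      "characteristic_interaction")]), 1)
  expect_error(method_attribution(list(fake_stage(list()))), "undefined")

  # all winners interaction -> share 1
  only <- entries[1:11]
  expect_equal(method_attribution(
    list(fake_stage(only), fake_stage(only)))$consistent[["interaction_share"]],
    1)
})

test_that("an implanted pathway with diffuse signal stays consistent", {
  study <- small_study(seed = 77, n_cases = 150, n_controls = 150,
                       effect_pathway = "pw_003", odds_ratio = 1.9)
  rep_ <- run_mip(study$dataset, study$structure,
                  thresholds = c(NA, 1e-3, 1e-4, 1e-5), n_perm = 300,
                  seed = 5)
  # no single SNP below 1e-3 exclusion wipes the modest per-SNP effects
  expect_true("pw_003" %in% rep_$consistent$pathway_id)
})

test_that("one ultra-significant SNP cannot keep a pathway consistent", {
  # null study, then implant a near-perfectly separating genotype into one
  # SNP of pw_001: significant with all SNPs, gone once p < 1e-3 SNPs are
  # excluded.
  study <- small_study(seed = 88, n_cases = 100, n_controls = 100)
  ds <- study$dataset
  pw_genes <- study$structure$catalog[["pw_001"]]$genes
  pw_snps <- unique(unlist(
    study$structure$snp_gene$gene_to_snps[pw_genes]))
  # identical genotype distribution in cases and controls: exactly null
  balanced <- rep(c(0L, 1L, 2L, 1L, 0L), each = 20)
  for (s in pw_snps)
    ds$genotypes[, match(s, ds$snps$snp_id)] <- balanced
  snp <- pw_snps[1]
  j <- match(snp, ds$snps$snp_id)
  ds$genotypes[, j] <- c(rep(2L, 95), rep(1L, 10), rep(0L, 95))
  expect_lt(allelic_association(ds)$p_value[j], 1e-5)
  rep_ <- run_mip(ds, study$structure, thresholds = c(NA, 1e-3, 1e-4, 1e-5),
                  n_perm = 300, seed = 11)
  expect_true("pw_001" %in% names(rep_$stages[[1]]$best))
  for (k in 2:4)
    expect_false("pw_001" %in% names(rep_$stages[[k]]$best))
  expect_false("pw_001" %in% rep_$consistent$pathway_id)
})

test_that("identical master seeds give identical serialized reports", {
  study <- small_study(seed = 31, effect_pathway = "pw_001",
                       odds_ratio = 1.6)
  r1 <- run_mip(study$dataset, study$structure, n_perm = 100, seed = 42)
  r2 <- run_mip(study$dataset, study$structure, n_perm = 100, seed = 42)
  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  write_mip_report(r1, d1)
  write_mip_report(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_identical(sort(list.files(d1)), sort(list.files(d2)))
  expect_true("manifest.json" %in% list.files(d1))
})
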