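# Genotype quality control and single-marker association.

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact two-sided SNP-HWE test in the style of Wigginton, Cutler and
#' Abecasis (2005): conditional on the observed allele counts, the p-value is
#' the total probability of all heterozygote configurations whose probability
#' does not exceed that of the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous, heterozygous,
#'   homozygous other).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("HWE test undefined for all-zero genotype counts")
  n_a <- 2L * n_aa + n_Aa            # minor-ish allele count (either works)
  n_A <- 2L * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0L) return(1)          # monomorphic: single possible table
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  log_prob <- hets * log(2) + lfactorial(n) -
    lfactorial((n_A - hets) / 2) - lfactorial(hets) -
    lfactorial((n_a - hets) / 2) +
    lfactorial(n_A) + lfactorial(n_a) - lfactorial(2L * n)
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Per-SNP allelic association test
#'
#' The basic single-marker allelic test: for each SNP a 2x2 allele-count
#' table (allele1/allele2 by case/control) is formed from non-missing
#' genotypes and scored with the 1-df Pearson chi-square statistic, no
#' continuity correction. A SNP that is monomorphic, or has no non-missing
#' calls in one phenotype group, carries no information and is assigned
#' p = 1 by convention.
#'
#' @param ds a [genotype_dataset()] with at least one case and one control.
#' @return data frame with columns `snp_id`, `chi_square`, `p_value`.
#' @export
allelic_association <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  is_case <- ds$phenotype == "case"
  if (!any(is_case) || all(is_case))
    stop("association test needs at least one case and one control")
  stat <- .allelic_chisq_matrix(ds$genotypes,
                                matrix(as.numeric(is_case), nrow = 1))
  data.frame(snp_id = ds$snps$snp_id,
             chi_square = as.numeric(stat$chisq),
             p_value = as.numeric(stat$p),
             stringsAsFactors = FALSE)
}

# Vectorised allelic chi-square for many case-label assignments at once.
# genotypes: samples x snps dosage matrix (NA = missing);
# case_ind: n_assignments x samples 0/1 matrix (rows = label assignments).
# Returns list(chisq, p, logp) of n_assignments x snps matrices, where logp
# is -2*log(p) with p floored at 1e-300. All assignments flow through the
# same arithmetic, so identical allele tables give bit-identical statistics.
.allelic_chisq_matrix <- function(genotypes, case_ind) {
  M <- genotypes
  M[is.na(M)] <- 0L
  storage.mode(M) <- "double"
  Z <- (!is.na(genotypes)) * 1.0
  tot_a1 <- colSums(M)                    # allele1 count over everyone
  tot_alleles <- 2 * colSums(Z)

  a <- case_ind %*% M                     # allele1 in cases
  n_case_alleles <- 2 * (case_ind %*% Z)
  b <- n_case_alleles - a                 # allele2 in cases
  cc <- rep(tot_a1, each = nrow(a)); dim(cc) <- dim(a)
  cc <- cc - a                            # allele1 in controls
  n_tot <- rep(tot_alleles, each = nrow(a)); dim(n_tot) <- dim(a)
  d <- n_tot - n_case_alleles - cc        # allele2 in controls

  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  num <- n_tot * (a * d - b * cc)^2
  chisq <- matrix(0, nrow(a), ncol(a))
  ok <- denom > 0
  chisq[ok] <- num[ok] / denom[ok]
  p <- matrix(1, nrow(a), ncol(a))
  p[ok] <- stats::pchisq(chisq[ok], df = 1, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  list(chisq = chisq, p = p, logp = -2 * log(p))
}

#' Apply genotype quality-control filters
#'
#' Filters are applied in a fixed, documented order so that the report is
#' deterministic: (1) samples with a missing-call fraction above
#' `max_missing` are removed; (2) SNPs with a missing-call fraction above
#' `max_missing` are removed; (3) SNPs with minor allele frequency below
#' `min_maf` are removed; (4) SNPs failing the exact Hardy-Weinberg test in
#' controls at `hwe_alpha` are removed. Thresholds are exclusive on the
#' stated side: a SNP is removed when missingness > `max_missing`, when
#' MAF < `min_maf`, or when the HWE p-value < `hwe_alpha`.
#'
#' @param ds a [genotype_dataset()].
#' @param max_missing maximum tolerated missing-call fraction (default 0.05).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param hwe_alpha significance level for the exact HWE test in controls
#'   (default 1e-3).
#' @return list with elements `dataset` (the filtered [genotype_dataset()])
#'   and `report` (a `qc_report` with before/after counts and per-criterion
#'   removals).
#' @export
apply_qc_filters <- function(ds, max_missing = 0.05, min_maf = 0.05,
                             hwe_alpha = 1e-3) {
  stopifnot(inherits(ds, "genotype_dataset"))
  for (thr in c(max_missing, min_maf, hwe_alpha))
    if (thr < 0 || thr > 1) stop("QC thresholds must lie in [0, 1]")
  n_snps_in <- nrow(ds$snps)
  n_samples_in <- length(ds$sample_ids)

  # (1) sample missingness
  smiss <- rowMeans(is.na(ds$genotypes))
  keep_samples <- smiss <= max_missing
  removed_samples <- sum(!keep_samples)
  if (!any(keep_samples)) stop("QC removed every sample (missingness)")
  ds <- subset_dataset(ds, samples = keep_samples)
  if (!any(ds$phenotype == "case") || !any(ds$phenotype == "control"))
    stop("QC left no cases or no controls")

  # (2) SNP missingness
  vmiss <- colMeans(is.na(ds$genotypes))
  keep <- vmiss <= max_missing
  removed_by_missingness <- sum(!keep)
  ds <- subset_dataset(ds, snps = keep)

  # (3) minor allele frequency over all non-missing calls
  a1 <- colSums(ds$genotypes, na.rm = TRUE)
  n_called <- colSums(!is.na(ds$genotypes))
  freq <- ifelse(n_called > 0, a1 / (2 * n_called), 0)
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= min_maf
  removed_by_maf <- sum(!keep)
  ds <- subset_dataset(ds, snps = keep)

  # (4) exact HWE in controls
  ctrl <- ds$genotypes[ds$phenotype == "control", , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(ctrl)), function(j) {
    g <- ctrl[, j]; g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 2L), sum(g == 1L), sum(g == 0L))
  }, numeric(1))
  keep <- hwe_p >= hwe_alpha
  removed_by_hwe <- sum(!keep)
  if (!any(keep)) stop("QC removed every SNP")
  ds <- subset_dataset(ds, snps = keep)

  report <- structure(
    list(n_snps_in = n_snps_in, n_snps_out = nrow(ds$snps),
         n_samples_in = n_samples_in, n_samples_out = length(ds$sample_ids),
         removed_samples_by_missingness = removed_samples,
         removed_by_missingness = removed_by_missingness,
         removed_by_maf = removed_by_maf,
         removed_by_hwe = removed_by_hwe),
    class = "qc_report")
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  samples: ", x$n_samples_in, " -> ", x$n_samples_out,
      " (", x$removed_samples_by_missingness, " removed, missingness)\n",
      sep = "")
  cat("  SNPs:    ", x$n_snps_in, " -> ", x$n_snps_out, "\n", sep = "")
  cat("    removed by missingness:", x$removed_by_missingness, "\n")
  cat("    removed by MAF:        ", x$removed_by_maf, "\n")
  cat("    removed by HWE:        ", x$removed_by_hwe, "\n")
  invisible(x)
}
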