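# Permutation variant of Fisher's combined probability test for SNP sets.
#
# The observed statistic T = sum over set SNPs of -2*log(p_snp) is compared
# against the same statistic recomputed under case/control labels permuted
# jointly across all samples. Label permutation (rather than drawing random
# SNPs) preserves the linkage-disequilibrium structure among the set's SNPs
# under the null.

#' Fisher's combined probability statistic
#'
#' @param p_values numeric vector of per-SNP p-values in (0, 1]. Values
#'   below 1e-300 are clamped before taking logs so the statistic stays
#'   finite.
#' @return `T = sum(-2 * log(p))`, a non-negative scalar.
#' @export
fisher_combined <- function(p_values) {
  if (!length(p_values)) stop("fisher_combined needs a non-empty p-value set")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  sum(-2 * log(pmax(p_values, 1e-300)))
}

# n_perm x n_samples 0/1 matrix of random case-label assignments preserving
# the observed number of cases. Reproducible from `seed` and independent of
# which SNP sets are later scored.
.make_label_permutations <- function(n_samples, n_cases, n_perm, seed) {
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(0, nrow = n_perm, ncol = n_samples)
  for (i in seq_len(n_perm))
    P[i, sample.int(n_samples, n_cases)] <- 1
  P
}

# All distinct case/control assignments as an N x n_samples 0/1 matrix.
.enumerate_label_assignments <- function(n_samples, n_cases,
                                         max_arrangements = 200000) {
  n_arr <- choose(n_samples, n_cases)
  if (n_arr > max_arrangements)
    stop("refusing to enumerate ", n_arr, " label arrangements (limit ",
         max_arrangements, ")")
  combos <- utils::combn(n_samples, n_cases)
  P <- matrix(0, nrow = ncol(combos), ncol = n_samples)
  for (i in seq_len(ncol(combos))) P[i, combos[, i]] <- 1
  P
}

.check_set_snps <- function(set, ds) {
  missing <- setdiff(set$snp_ids, ds$snps$snp_id)
  if (length(missing))
    stop("pathway set ", set$set_id, " names SNP(s) absent from the ",
         "dataset: ", paste(utils::head(missing, 5), collapse = ", "))
}

.new_set_result <- function(set, statistic, n_perm, r, p_value, method) {
  structure(list(pathway_set = set, pathway_id = set$pathway_id,
                 family = set$family, tier = set$tier, set_id = set$set_id,
                 statistic = statistic, n_perm = as.integer(n_perm),
                 r = as.integer(r),
                 p_value = p_value, method = method),
            class = "set_result")
}

#' @export
print.set_result <- function(x, ...) {
  cat("set_result ", x$set_id, ": T = ", format(x$statistic, digits = 6),
      ", ", x$r, "/", x$n_perm, " exceedances, p ",
      format_set_pvalue(x), "\n", sep = "")
  invisible(x)
}

#' Display convention for permutation p-values
#'
#' When no permutation reached the observed statistic the estimate sits at
#' the resolution floor of the permutation scheme, and is displayed as
#' `"<= floor"` rather than as a point value.
#'
#' @param result a `set_result`.
#' @return character scalar, e.g. `"= 3.0e-03"` or `"<= 2.0e-04"`.
#' @export
format_set_pvalue <- function(result) {
  if (result$method == "sampled" && result$r == 0L)
    paste0("<= ", format(result$p_value, digits = 2, scientific = TRUE))
  else paste0("= ", format(result$p_value, digits = 2, scientific = TRUE))
}

# Core scorer: given the observed labels and a matrix of null label
# assignments, compute T for every assignment and every set at once.
# sets: list of pathway_set; returns list(T_obs, T_null) with T_null a
# matrix (assignments x sets). Observed labels ride through the identical
# arithmetic as the null assignments so that tied allele tables give
# bit-identical statistics.
.score_sets_core <- function(sets, ds, null_assignments) {
  union_snps <- unique(unlist(lapply(sets, `[[`, "snp_ids"),
                              use.names = FALSE))
  col_idx <- match(union_snps, ds$snps$snp_id)
  G <- ds$genotypes[, col_idx, drop = FALSE]
  obs <- matrix(as.numeric(ds$phenotype == "case"), nrow = 1)
  stats <- .allelic_chisq_matrix(G, rbind(obs, null_assignments))
  logp <- stats$logp
  T_obs <- numeric(length(sets))
  T_null <- matrix(0, nrow = nrow(null_assignments), ncol = length(sets))
  for (k in seq_along(sets)) {
    j <- match(sets[[k]]$snp_ids, union_snps)
    Tk <- rowSums(logp[, j, drop = FALSE])
    T_obs[k] <- Tk[1]
    T_null[, k] <- Tk[-1]
  }
  list(T_obs = T_obs, T_null = T_null)
}

#' Permutation set p-value for one pathway set
#'
#' Computes the observed combined statistic, recomputes it under `n_perm`
#' random case/control label permutations (each preserving the case count),
#' counts the permutations whose statistic reaches or exceeds the observed
#' one (ties count, the conservative convention), and reports
#' `p = (r + 1) / (n_perm + 1)`. With `exhaustive = TRUE` all distinct
#' label arrangements are enumerated instead and `p = r / N` over the full
#' enumeration (which contains the observed labels, so `r >= 1`).
#'
#' @param set a `pathway_set` whose SNPs are all present in `ds`.
#' @param ds a [genotype_dataset()].
#' @param n_perm number of random label permutations (default 5000).
#' @param seed RNG seed for the permutation stream.
#' @param permutations optional precomputed 0/1 label matrix
#'   (permutations x samples), e.g. one stream shared across all sets of a
#'   run; overrides `n_perm` and `seed`.
#' @param exhaustive enumerate every distinct label arrangement (exact
#'   test; sample counts must keep `choose(n, n_cases)` below
#'   `max_arrangements`).
#' @param max_arrangements safety bound for `exhaustive` (default 200000).
#' @return a `set_result` with fields `statistic`, `n_perm`, `r`,
#'   `p_value`.
#' @export
permutation_set_pvalue <- function(set, ds, n_perm = 5000, seed = NULL,
                                   permutations = NULL, exhaustive = FALSE,
                                   max_arrangements = 200000) {
  stopifnot(inherits(set, "pathway_set"), inherits(ds, "genotype_dataset"))
  .check_set_snps(set, ds)
  n_cases <- sum(ds$phenotype == "case")
  n_samples <- length(ds$sample_ids)
  if (exhaustive) {
    P <- .enumerate_label_assignments(n_samples, n_cases, max_arrangements)
    sc <- .score_sets_core(list(set), ds, P)
    r <- sum(sc$T_null[, 1] >= sc$T_obs[1])
    return(.new_set_result(set, sc$T_obs[1], nrow(P), r, r / nrow(P),
                           "exhaustive"))
  }
  if (is.null(permutations)) {
    if (n_perm < 1) stop("n_perm must be at least 1")
    permutations <- .make_label_permutations(n_samples, n_cases, n_perm, seed)
  }
  n_perm <- nrow(permutations)
  sc <- .score_sets_core(list(set), ds, permutations)
  r <- sum(sc$T_null[, 1] >= sc$T_obs[1])
  .new_set_result(set, sc$T_obs[1], n_perm, r, (r + 1) / (n_perm + 1),
                  "sampled")
}

#' Exact permutation p-value by independent enumeration
#'
#' Ground-truth oracle for [permutation_set_pvalue()]: loops over every
#' distinct case/control assignment, rebuilding each SNP's 2x2 allele table
#' by direct counting and evaluating the textbook Pearson chi-square
#' formula, with no shared code with the vectorised scorer.
#'
#' @inheritParams permutation_set_pvalue
#' @return a `set_result` with `p_value = r / N` over the `N` enumerated
#'   arrangements.
#' @export
exact_permutation_pvalue <- function(set, ds, max_arrangements = 200000) {
  stopifnot(inherits(set, "pathway_set"), inherits(ds, "genotype_dataset"))
  .check_set_snps(set, ds)
  n <- length(ds$sample_ids)
  k <- sum(ds$phenotype == "case")
  n_arr <- choose(n, k)
  if (n_arr > max_arrangements)
    stop("refusing to enumerate ", n_arr, " label arrangements (limit ",
         max_arrangements, ")")
  G <- ds$genotypes[, match(set$snp_ids, ds$snps$snp_id), drop = FALSE]
  stat_for <- function(case_idx) {
    total <- 0
    for (j in seq_len(ncol(G))) {
      g <- G[, j]
      gc <- g[case_idx]; gc <- gc[!is.na(gc)]
      gu <- g[-case_idx]; gu <- gu[!is.na(gu)]
      a <- sum(gc); b <- 2 * length(gc) - a
      cc <- sum(gu); d <- 2 * length(gu) - cc
      N <- a + b + cc + d
      denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
      p <- if (denom > 0) {
        max(stats::pchisq(N * (a * d - b * cc)^2 / denom, df = 1,
                          lower.tail = FALSE), 1e-300)
      } else 1
      total <- total + (-2 * log(p))
    }
    total
  }
  T_obs <- stat_for(which(ds$phenotype == "case"))
  combos <- utils::combn(n, k)
  T_all <- vapply(seq_len(ncol(combos)),
                  function(i) stat_for(combos[, i]), numeric(1))
  r <- sum(T_all >= T_obs)
  .new_set_result(set, T_obs, n_arr, r, r / n_arr, "exhaustive")
}

#' Score many pathway sets in one run
#'
#' With `shared_permutations = TRUE` (the default) a single permutation
#' stream derived from `seed` is reused for every set, which makes set
#' p-values directly comparable within a run and lets the per-permutation
#' SNP statistics be computed once over the union of all set SNPs. With
#' `shared_permutations = FALSE` each set gets its own stream, seeded by a
#' documented split: `set.seed(seed)` followed by one `sample.int` draw per
#' set in set order.
#'
#' @param sets flat list of `pathway_set` objects (or the nested result of
#'   [enumerate_all_sets()], which is flattened).
#' @inheritParams permutation_set_pvalue
#' @param shared_permutations reuse one label-permutation stream across all
#'   sets (default `TRUE`).
#' @return list of `set_result`, one per set, in input order.
#' @export
score_pathway_sets <- function(sets, ds, n_perm = 5000, seed = NULL,
                               shared_permutations = TRUE) {
  if (length(sets) && !inherits(sets[[1]], "pathway_set"))
    sets <- unlist(sets, recursive = FALSE, use.names = FALSE)
  if (!length(sets)) return(list())
  for (s in sets) .check_set_snps(s, ds)
  n_cases <- sum(ds$phenotype == "case")
  n_samples <- length(ds$sample_ids)
  if (shared_permutations) {
    P <- .make_label_permutations(n_samples, n_cases, n_perm, seed)
    sc <- .score_sets_core(sets, ds, P)
    out <- vector("list", length(sets))
    for (k in seq_along(sets)) {
      r <- sum(sc$T_null[, k] >= sc$T_obs[k])
      out[[k]] <- .new_set_result(sets[[k]], sc$T_obs[k], n_perm, r,
                                  (r + 1) / (n_perm + 1), "sampled")
    }
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  set_seeds <- sample.int(.Machine$integer.max, length(sets))
  lapply(seq_along(sets), function(k)
    permutation_set_pvalue(sets[[k]], ds, n_perm = n_perm,
                           seed = set_seeds[k]))
}

#' Tabulate set results
#'
#' @param results list of `set_result`.
#' @return data frame with one row per set: identifiers, statistic,
#'   exceedance count, permutation count, p-value and its display form.
#' @export
set_results_table <- function(results) {
  if (!length(results))
    return(data.frame(pathway_id = character(), family = character(),
                      tier = character(), set_id = character(),
                      n_genes = integer(), n_snps = integer(),
                      statistic = numeric(), r = integer(),
                      n_perm = integer(), p_value = numeric(),
                      p_display = character()))
  do.call(rbind, lapply(results, function(x)
    data.frame(pathway_id = x$pathway_id, family = x$family, tier = x$tier,
               set_id = x$set_id,
               n_genes = length(x$pathway_set$gene_ids),
               n_snps = length(x$pathway_set$snp_ids),
               statistic = x$statistic, r = x$r, n_perm = x$n_perm,
               p_value = x$p_value, p_display = format_set_pvalue(x),
               stringsAsFactors = FALSE)))
}
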