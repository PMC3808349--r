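# Four-stage multistage integrative pathway (MIP) analysis: score every
# pathway set on all SNPs, then three more times after excluding SNPs whose
# single-marker p-value falls below 1e-3, 1e-4 and 1e-5, and intersect the
# per-stage best lists to find pathways whose significance does not hinge
# on a few top markers.

#' Best list: one winning set per pathway
#'
#' For each pathway, the set with the smallest p-value is retained if and
#' only if that p-value is at most `alpha`. Ties at the minimal p are
#' broken deterministically: larger SNP count first, then family/tier
#' precedence (simple > interaction > characteristic >
#' characteristic-interaction, tiers low to ultra), then lexical set id.
#'
#' @param results list of `set_result` (one stage's scored sets).
#' @param alpha significance cutoff (default 0.05).
#' @return named list mapping pathway id to its winning `set_result`.
#' @export
best_list <- function(results, alpha = 0.05) {
  if (!length(results)) return(list())
  fam_rank <- c(simple = 1, interaction = 2, characteristic = 3,
                characteristic_interaction = 4)
  tier_rank <- c(none = 0, low = 1, medium = 2, high = 3, ultra = 4)
  by_pw <- split(results, vapply(results, `[[`, character(1), "pathway_id"))
  out <- list()
  for (pw in names(by_pw)) {
    rs <- by_pw[[pw]]
    p <- vapply(rs, `[[`, numeric(1), "p_value")
    n_snps <- vapply(rs, function(x) length(x$pathway_set$snp_ids),
                     integer(1))
    fr <- fam_rank[vapply(rs, `[[`, character(1), "family")]
    tr <- tier_rank[vapply(rs, `[[`, character(1), "tier")]
    ids <- vapply(rs, `[[`, character(1), "set_id")
    o <- order(p, -n_snps, fr, tr, ids)[1]
    if (p[o] <= alpha) out[[pw]] <- rs[[o]]
  }
  if (!length(out)) return(out)
  out[order(names(out))]
}

#' Run one MIP stage
#'
#' Computes per-SNP allelic p-values once from the observed labels, drops
#' SNPs with `p < exclusion_threshold` (no exclusion when the threshold is
#' `NULL`/`NA`), rebuilds the pathway sets on the surviving SNP universe,
#' scores every surviving set and extracts the best list. Set membership is
#' fixed before scoring; permutations inside the stage never re-decide it.
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param structure the [build_layered_structure()] result for `ds`.
#' @param exclusion_threshold drop SNPs whose observed single-marker
#'   p-value is strictly below this; `NULL` or `NA` keeps all SNPs.
#' @param n_perm permutations per set (default 5000).
#' @param seed RNG seed for the stage's shared permutation stream.
#' @param alpha best-list significance cutoff (default 0.05).
#' @param dedup,min_set_size passed to [enumerate_all_sets()].
#' @param shared_permutations see [score_pathway_sets()].
#' @return a `stage_result`: list with `exclusion_threshold`,
#'   `n_snps_used`, `results` (list of `set_result`), `best`
#'   (the [best_list()]), and `table` (the [set_results_table()]).
#' @export
run_stage <- function(ds, structure, exclusion_threshold = NULL,
                      n_perm = 5000, seed = NULL, alpha = 0.05,
                      dedup = TRUE, min_set_size = 2,
                      shared_permutations = TRUE) {
  stopifnot(inherits(ds, "genotype_dataset"),
            inherits(structure, "layered_structure"))
  thr <- exclusion_threshold
  if (!is.null(thr) && is.na(thr)) thr <- NULL
  if (!is.null(thr) && (thr <= 0 || thr >= 1))
    stop("exclusion_threshold must lie in (0, 1)")
  assoc <- allelic_association(ds)
  if (is.null(thr)) {
    keep <- rep(TRUE, nrow(assoc))
  } else {
    keep <- assoc$p_value >= thr     # exclusion is strict: p < thr removed
  }
  stage_ds <- subset_dataset(ds, snps = keep)
  stage_structure <- restrict_structure(structure, stage_ds$snps$snp_id)
  sets <- enumerate_all_sets(stage_structure, dedup = dedup,
                             min_set_size = min_set_size)
  flat <- unlist(sets, recursive = FALSE, use.names = FALSE)
  if (!length(flat)) {
    warning("no pathway set survived the minimum-size rule in this stage")
    results <- list()
  } else {
    results <- score_pathway_sets(flat, stage_ds, n_perm = n_perm,
                                  seed = seed,
                                  shared_permutations = shared_permutations)
  }
  base::structure(list(exclusion_threshold = if (is.null(thr)) NA_real_ else thr,
                 n_snps_used = sum(keep),
                 results = results,
                 best = best_list(results, alpha = alpha),
                 table = set_results_table(results),
                 alpha = alpha),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  thr <- if (is.na(x$exclusion_threshold)) "none"
         else format(x$exclusion_threshold, scientific = TRUE)
  cat("stage_result: exclusion threshold ", thr, ", ", x$n_snps_used,
      " SNPs, ", length(x$results), " sets scored, ", length(x$best),
      " pathways in best list (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Run the full multistage analysis
#'
#' Executes one stage per entry of `thresholds` (by default: no exclusion,
#' then 1e-3, 1e-4, 1e-5), derives per-stage seeds from the master seed by
#' a documented split (`set.seed(seed)` followed by one `sample.int` draw
#' per stage, in stage order), then computes the consistency intersection
#' and the per-family method attribution.
#'
#' @inheritParams run_stage
#' @param thresholds vector of exclusion thresholds, `NA` meaning "all
#'   SNPs" (default `c(NA, 1e-3, 1e-4, 1e-5)`).
#' @param seed master seed; per-stage permutation streams are derived from
#'   it and depend only on stage order, so adding a pathway to the catalog
#'   never perturbs other pathways' results.
#' @return a `mip_report`: list with `stages`, `consistent`
#'   (see [consistent_pathways()]), `attribution`
#'   (see [method_attribution()]), and `params`.
#' @export
run_mip <- function(ds, structure, thresholds = c(NA, 1e-3, 1e-4, 1e-5),
                    n_perm = 5000, seed = NULL, alpha = 0.05, dedup = TRUE,
                    min_set_size = 2, shared_permutations = TRUE) {
  if (!length(thresholds)) stop("at least one stage threshold is required")
  if (!is.null(seed)) set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, length(thresholds))
  stages <- lapply(seq_along(thresholds), function(i)
    run_stage(ds, structure,
              exclusion_threshold = if (is.na(thresholds[i])) NULL
                                    else thresholds[i],
              n_perm = n_perm, seed = stage_seeds[i], alpha = alpha,
              dedup = dedup, min_set_size = min_set_size,
              shared_permutations = shared_permutations))
  consistent <- consistent_pathways(stages)
  attribution <- tryCatch(method_attribution(stages),
                          error = function(e) NULL)
  base::structure(list(stages = stages, consistent = consistent,
                 attribution = attribution,
                 params = list(thresholds = thresholds, n_perm = n_perm,
                               seed = seed, alpha = alpha, dedup = dedup,
                               min_set_size = min_set_size,
                               shared_permutations = shared_permutations)),
            class = "mip_report")
}

#' Pathways significant in every stage
#'
#' A pathway is consistently significant when it appears in the best list
#' of every stage, i.e. has some set with p below the cutoff in all runs.
#'
#' @param stages list of `stage_result` (at least two).
#' @return data frame: `pathway_id` plus one p-value column per stage
#'   (`p_all`, `p_<threshold>`), rows sorted by pathway id.
#' @export
consistent_pathways <- function(stages) {
  if (inherits(stages, "mip_report")) stages <- stages$stages
  if (length(stages) < 2)
    stop("consistency needs at least two stages")
  keys <- lapply(stages, function(s) names(s$best))
  common <- sort(Reduce(intersect, keys))
  cols <- lapply(stages, function(s)
    vapply(common, function(pw) s$best[[pw]]$p_value, numeric(1)))
  labels <- vapply(stages, function(s)
    if (is.na(s$exclusion_threshold)) "p_all"
    else paste0("p_", format(s$exclusion_threshold, scientific = TRUE)),
    character(1))
  out <- data.frame(pathway_id = common, stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[labels[i]]] <- as.numeric(cols[[i]])
  rownames(out) <- NULL
  out
}

#' Which set family wins the best lists
#'
#' Fraction of best-list entries per set family, per stage and for the
#' consistent pathways (family taken from the all-SNPs stage winner). The
#' interaction share — interaction plus characteristic-interaction — is
#' reported alongside.
#'
#' @param stages list of `stage_result`, or a `mip_report`.
#' @return list with `per_stage` (data frame stage x family fractions) and
#'   `consistent` (named fractions over consistent pathways' winning
#'   families, with `interaction_share`).
#' @export
method_attribution <- function(stages) {
  report <- NULL
  if (inherits(stages, "mip_report")) { report <- stages; stages <- stages$stages }
  families <- c("simple", "characteristic", "interaction",
                "characteristic_interaction")
  if (!length(stages) || !any(vapply(stages, function(s) length(s$best) > 0,
                                     logical(1))))
    stop("method attribution undefined for empty best lists")
  frac_of <- function(best) {
    fams <- vapply(best, `[[`, character(1), "family")
    tab <- table(factor(fams, levels = families))
    as.numeric(tab) / length(fams)
  }
  per_stage <- do.call(rbind, lapply(seq_along(stages), function(i) {
    s <- stages[[i]]
    if (!length(s$best)) return(NULL)
    fr <- frac_of(s$best)
    data.frame(stage = i,
               exclusion_threshold = s$exclusion_threshold,
               simple = fr[1], characteristic = fr[2], interaction = fr[3],
               characteristic_interaction = fr[4],
               interaction_share = fr[3] + fr[4])
  }))
  common <- if (!is.null(report)) report$consistent$pathway_id
            else consistent_pathways(stages)$pathway_id
  consistent <- NULL
  if (length(common)) {
    first <- stages[[1]]$best[common]
    fr <- frac_of(first)
    names(fr) <- families
    consistent <- c(fr, interaction_share = unname(fr[3] + fr[4]))
  }
  list(per_stage = per_stage, consistent = consistent)
}

#' @export
print.mip_report <- function(x, ...) {
  cat("mip_report:", length(x$stages), "stages\n")
  for (s in x$stages) print(s)
  cat(nrow(x$consistent), "consistently significant pathway(s)\n")
  if (nrow(x$consistent)) print(x$consistent)
  invisible(x)
}

#' Serialize a MIP report to a directory
#'
#' Writes per-stage full result tables and best lists, the
#' consistent-pathways table, the attribution summary, and a JSON manifest
#' of run parameters.
#'
#' @param report a `mip_report`.
#' @param dir output directory (created if absent).
#' @param qc_report optional `qc_report` to embed in the manifest.
#' @return `dir`, invisibly.
#' @export
write_mip_report <- function(report, dir, qc_report = NULL) {
  stopifnot(inherits(report, "mip_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(report$stages)) {
    s <- report$stages[[i]]
    utils::write.table(s$table, file.path(dir,
      sprintf("stage%d_results.tsv", i)), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(set_results_table(unname(s$best)), file.path(dir,
      sprintf("stage%d_best_list.tsv", i)), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  utils::write.table(report$consistent,
                     file.path(dir, "consistent_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$attribution) &&
      !is.null(report$attribution$per_stage))
    utils::write.table(report$attribution$per_stage,
                       file.path(dir, "attribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(package = "mipgwas",
                   version = as.character(utils::packageVersion("mipgwas")),
                   params = report$params,
                   qc = if (!is.null(qc_report)) unclass(qc_report) else NULL,
                   n_stages = length(report$stages),
                   n_consistent = nrow(report$consistent))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}
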