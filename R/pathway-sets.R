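# Construction of the four families of pathway-based SNP sets.
#
# simple                      all SNPs of all genes in the pathway
# characteristic              only genes occurring exclusively in the pathway
# interaction (4 tiers)       genes filtered by interaction class:
#                               ultra = {EV}, high = {EV,HC},
#                               medium = {EV,HC,MC}, low = {EV,HC,MC,LC}
# characteristic_interaction  both filters at once (4 tiers)
#
# The low tier is the superset of the interaction tiers by construction;
# genes of class NONE appear only in simple/characteristic sets.

.tier_classes <- list(ultra = "EV",
                      high = c("EV", "HC"),
                      medium = c("EV", "HC", "MC"),
                      low = c("EV", "HC", "MC", "LC"))

# canonical family/tier precedence: the label kept when identical SNP sets
# are collapsed, and the deterministic output order. Least-restrictive
# definitions come first.
.set_precedence <- data.frame(
  family = c("simple", "characteristic",
             rep("interaction", 4), rep("characteristic_interaction", 4)),
  tier = c("none", "none", "low", "medium", "high", "ultra",
           "low", "medium", "high", "ultra"),
  stringsAsFactors = FALSE)

.new_pathway_set <- function(pathway_id, family, tier, gene_ids, snp_ids) {
  structure(list(pathway_id = pathway_id, family = family, tier = tier,
                 set_id = paste(pathway_id, family, tier, sep = ":"),
                 gene_ids = sort(unique(gene_ids)),
                 snp_ids = sort(unique(snp_ids))),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat("pathway_set ", x$set_id, ": ", length(x$gene_ids), " genes, ",
      length(x$snp_ids), " SNPs\n", sep = "")
  invisible(x)
}

#' Build the SNP sets of one pathway
#'
#' Derives up to ten candidate sets (1 simple + 1 characteristic + 4
#' interaction tiers + 4 characteristic-interaction tiers) for one pathway.
#' Exclusivity for the characteristic variants is judged against every
#' pathway of the loaded catalog. With `dedup = TRUE` (the default),
#' candidates with identical SNP content are collapsed, keeping the
#' least-restrictive representative (simple > characteristic >
#' interaction low..ultra > characteristic-interaction low..ultra). Empty
#' sets and sets below `min_set_size` SNPs are discarded.
#'
#' @param structure a [build_layered_structure()] result.
#' @param pathway_id pathway to build sets for; must exist in the catalog.
#' @param dedup collapse SNP-identical set variants (default `TRUE`).
#' @param min_set_size smallest SNP count a set may have (default 2).
#' @return list of `pathway_set` objects in precedence order.
#' @export
build_sets_for_pathway <- function(structure, pathway_id, dedup = TRUE,
                                   min_set_size = 2) {
  stopifnot(inherits(structure, "layered_structure"))
  pw <- structure$catalog[[pathway_id]]
  if (is.null(pw)) stop("pathway not in catalog: ", pathway_id)
  genes <- pw$genes
  cls <- structure$gene_class[genes]
  exclusive <- vapply(genes, function(g)
    length(structure$gene_pathways[[g]]) == 1L, logical(1))
  snps_of <- function(gs) {
    unique(unlist(structure$snp_gene$gene_to_snps[gs], use.names = FALSE))
  }
  candidates <- vector("list", nrow(.set_precedence))
  for (i in seq_len(nrow(.set_precedence))) {
    fam <- .set_precedence$family[i]
    tier <- .set_precedence$tier[i]
    keep <- rep(TRUE, length(genes))
    if (fam %in% c("characteristic", "characteristic_interaction"))
      keep <- keep & exclusive
    if (fam %in% c("interaction", "characteristic_interaction"))
      keep <- keep & cls %in% .tier_classes[[tier]]
    gs <- genes[keep]
    candidates[[i]] <- .new_pathway_set(pathway_id, fam, tier, gs,
                                        snps_of(gs))
  }
  sizes <- vapply(candidates, function(s) length(s$snp_ids), integer(1))
  candidates <- candidates[sizes >= max(1L, min_set_size)]
  if (dedup && length(candidates)) {
    keys <- vapply(candidates, function(s)
      paste(s$snp_ids, collapse = "\r"), character(1))
    candidates <- candidates[!duplicated(keys)]
  }
  candidates
}

#' Build the SNP sets of every pathway
#'
#' @inheritParams build_sets_for_pathway
#' @return named list mapping pathway id (lexical order) to its list of
#'   `pathway_set` objects; pathways whose every candidate set is empty or
#'   undersized map to an empty list.
#' @export
enumerate_all_sets <- function(structure, dedup = TRUE, min_set_size = 2) {
  stopifnot(inherits(structure, "layered_structure"))
  ids <- sort(names(structure$catalog))
  out <- lapply(ids, build_sets_for_pathway, structure = structure,
                dedup = dedup, min_set_size = min_set_size)
  names(out) <- ids
  out
}

#' Restrict a layered structure to a SNP universe
#'
#' Used by the sensitivity stages: the annotation, catalog and gene classes
#' are untouched, only the SNP layer shrinks, so pathway sets rebuilt from
#' the result contain surviving SNPs only.
#'
#' @param structure a `layered_structure`.
#' @param snp_ids SNPs to keep.
#' @return a new `layered_structure`.
#' @export
restrict_structure <- function(structure, snp_ids) {
  stopifnot(inherits(structure, "layered_structure"))
  keep <- intersect(structure$snp_ids, snp_ids)
  links <- structure$snp_gene$links
  sg <- suppressMessages(snp_gene_map(links[links$snp_id %in% keep, ,
                                            drop = FALSE], keep))
  out <- structure
  out$snp_ids <- keep
  out$snp_gene <- sg
  out
}

#' Dump pathway sets as a TSV table
#'
#' One row per set: pathway id, family, tier, gene and SNP counts and the
#' comma-joined SNP ids, for audit and fixtures.
#'
#' @param sets result of [enumerate_all_sets()] (or a flat list of
#'   `pathway_set` objects).
#' @param path output file; if `NULL` the data frame is returned only.
#' @return the table, invisibly when written.
#' @export
pathway_sets_table <- function(sets, path = NULL) {
  flat <- if (length(sets) && inherits(sets[[1]], "pathway_set")) sets
          else unlist(sets, recursive = FALSE, use.names = FALSE)
  tab <- do.call(rbind, lapply(flat, function(s) {
    data.frame(pathway_id = s$pathway_id, family = s$family, tier = s$tier,
               n_genes = length(s$gene_ids), n_snps = length(s$snp_ids),
               snp_ids = paste(s$snp_ids, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    tab <- data.frame(pathway_id = character(), family = character(),
                      tier = character(), n_genes = integer(),
                      n_snps = integer(), snp_ids = character())
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
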