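# The gene, protein, domain-interaction and pathway layers, and the per-gene
# interaction confidence class derived from pooled domain-domain interactions.

#' Domain-interaction confidence classes
#'
#' Ordered from highest to lowest confidence: `EV` (experimentally
#' validated), `HC` (high), `MC` (medium), `LC` (low); `NONE` marks genes
#' without any domain interaction.
#' @export
interaction_classes <- c("EV", "HC", "MC", "LC", "NONE")

#' Load a pathway catalog from a GMT file
#'
#' GMT dialect: tab-separated, one gene set per line — set id, description,
#' then member genes. Duplicate genes within a line are deduplicated and
#' empty lines are skipped.
#'
#' @param gmt_path path to the GMT file.
#' @return a `pathway_catalog`: named list of pathway entries, each a list
#'   with `pathway_id`, `name` and `genes` (character vector).
#' @export
load_pathway_catalog <- function(gmt_path) {
  if (!file.exists(gmt_path)) stop("file not found: ", gmt_path)
  lines <- readLines(gmt_path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty GMT file: ", gmt_path)
    return(structure(list(), class = "pathway_catalog"))
  }
  entries <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    id <- fields[1]
    if (!is.null(entries[[id]]))
      stop("duplicate pathway id in GMT: ", id)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT parse error at line ", i, ": pathway ", id, " has no genes")
    entries[[id]] <- list(pathway_id = id, name = fields[2], genes = genes)
  }
  structure(entries, class = "pathway_catalog")
}

#' Construct a pathway catalog in code
#'
#' @param sets named list mapping pathway id to a character vector of genes.
#' @param names optional named character vector of pathway display names.
#' @return a `pathway_catalog`.
#' @export
pathway_catalog <- function(sets, names = NULL) {
  out <- lapply(base::names(sets), function(id) {
    genes <- unique(as.character(sets[[id]]))
    if (!length(genes)) stop("pathway ", id, " has no genes")
    list(pathway_id = id,
         name = if (!is.null(names) && id %in% base::names(names))
           unname(names[[id]]) else id,
         genes = genes)
  })
  base::names(out) <- base::names(sets)
  structure(out, class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat("pathway_catalog with", length(x), "pathways\n")
  invisible(x)
}

#' Load a SNP-to-gene annotation table
#'
#' Reads a chip-annotation-style TSV with columns `snp_id`, `gene_id`,
#' `relation` (one of `coding`, `upstream`, `downstream`) and restricts it
#' to the SNPs present in the dataset. SNPs of the dataset absent from the
#' annotation remain unmapped (empty gene set) and never enter a pathway
#' set; annotation rows for unknown SNPs are dropped and counted.
#'
#' @param annotation_path path to the TSV (header required).
#' @param snp_ids character vector: the dataset's SNP universe.
#' @return a `snp_gene_map`: list with `links` (data frame `snp_id`,
#'   `gene_id`, `relation`), `snp_to_genes` and `gene_to_snps` (named lists),
#'   and `n_dropped` (annotation rows for SNPs outside the dataset).
#' @export
load_snp_gene_map <- function(annotation_path, snp_ids) {
  if (!file.exists(annotation_path)) stop("file not found: ", annotation_path)
  tab <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  needed <- c("snp_id", "gene_id", "relation")
  if (!all(needed %in% names(tab)))
    stop("annotation must have columns snp_id, gene_id, relation")
  snp_gene_map(tab, snp_ids)
}

#' Construct a SNP-to-gene map from a data frame
#'
#' @param links data frame with columns `snp_id`, `gene_id`, `relation`.
#' @param snp_ids the dataset's SNP universe.
#' @return a `snp_gene_map`; see [load_snp_gene_map()].
#' @export
snp_gene_map <- function(links, snp_ids) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  bad <- setdiff(unique(links$relation), c("coding", "upstream", "downstream"))
  if (length(bad))
    stop("unknown SNP-gene relation tag(s): ", paste(bad, collapse = ", "))
  inside <- links$snp_id %in% snp_ids
  n_dropped <- sum(!inside)
  if (n_dropped > 0)
    message(n_dropped, " annotation link(s) named SNPs absent from the ",
            "dataset and were dropped")
  links <- unique(links[inside, c("snp_id", "gene_id", "relation")])
  snp_to_genes <- lapply(split(links$gene_id, links$snp_id), unique)
  gene_to_snps <- lapply(split(links$snp_id, links$gene_id), unique)
  structure(list(links = links, snp_to_genes = snp_to_genes,
                 gene_to_snps = gene_to_snps, snp_ids = as.character(snp_ids),
                 n_dropped = n_dropped),
            class = "snp_gene_map")
}

#' Load the protein and domain-interaction layers
#'
#' @param gene_protein_path TSV with columns `gene_id`, `protein_id`.
#' @param protein_domain_path TSV with columns `protein_id`, `domain_id`.
#' @param domain_interaction_path TSV with columns `domain_a`, `domain_b`,
#'   `confidence` (one of EV/HC/MC/LC).
#' @return an `interaction_layers` object; see [interaction_layers()].
#' @export
load_interaction_layers <- function(gene_protein_path, protein_domain_path,
                                    domain_interaction_path) {
  gp <- utils::read.delim(gene_protein_path, stringsAsFactors = FALSE)
  pd <- utils::read.delim(protein_domain_path, stringsAsFactors = FALSE)
  di <- utils::read.delim(domain_interaction_path, stringsAsFactors = FALSE)
  interaction_layers(gp, pd, di)
}

#' Construct the protein/domain/interaction layers from data frames
#'
#' Domain interactions are undirected: the pair (a, b) is identified with
#' (b, a) and stored once under a canonical ordering.
#'
#' @param gene_protein data frame `gene_id`, `protein_id`.
#' @param protein_domain data frame `protein_id`, `domain_id`.
#' @param domain_interaction data frame `domain_a`, `domain_b`, `confidence`.
#' @return an `interaction_layers` object.
#' @export
interaction_layers <- function(gene_protein, protein_domain,
                               domain_interaction) {
  gp <- as.data.frame(gene_protein, stringsAsFactors = FALSE)
  pd <- as.data.frame(protein_domain, stringsAsFactors = FALSE)
  di <- as.data.frame(domain_interaction, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "protein_id") %in% names(gp)))
    stop("gene_protein needs columns gene_id, protein_id")
  if (!all(c("protein_id", "domain_id") %in% names(pd)))
    stop("protein_domain needs columns protein_id, domain_id")
  if (!all(c("domain_a", "domain_b", "confidence") %in% names(di)))
    stop("domain_interaction needs columns domain_a, domain_b, confidence")
  bad <- setdiff(unique(di$confidence), c("EV", "HC", "MC", "LC"))
  if (length(bad))
    stop("interaction confidence labels must be EV/HC/MC/LC; found: ",
         paste(bad, collapse = ", "))
  # canonical unordered pair; keep the most confident label on duplicates
  lo <- pmin(di$domain_a, di$domain_b)
  hi <- pmax(di$domain_a, di$domain_b)
  di <- data.frame(domain_a = lo, domain_b = hi,
                   confidence = factor(di$confidence,
                                       levels = c("EV", "HC", "MC", "LC")),
                   stringsAsFactors = FALSE)
  di <- di[order(di$domain_a, di$domain_b, di$confidence), , drop = FALSE]
  di <- di[!duplicated(di[c("domain_a", "domain_b")]), , drop = FALSE]
  rownames(di) <- NULL
  structure(list(
    gene_to_proteins = lapply(split(gp$protein_id, gp$gene_id), unique),
    protein_to_domains = lapply(split(pd$domain_id, pd$protein_id), unique),
    interactions = di),
    class = "interaction_layers")
}

#' Interaction confidence class of one gene
#'
#' Pools all domain-domain interactions that touch any domain of any protein
#' of the gene (each unordered domain pair counted once, no matter how many
#' of the gene's domains it involves) and returns the most confident class
#' `c` such that at least 50% of the pooled interactions have confidence
#' `c` or higher. Genes with no proteins, domains or interactions get
#' `"NONE"`.
#'
#' @param gene_id gene identifier.
#' @param layers an [interaction_layers()] object.
#' @return one of `"EV"`, `"HC"`, `"MC"`, `"LC"`, `"NONE"`.
#' @export
assign_interaction_class <- function(gene_id, layers) {
  stopifnot(inherits(layers, "interaction_layers"))
  proteins <- layers$gene_to_proteins[[gene_id]]
  if (is.null(proteins)) return("NONE")
  domains <- unique(unlist(layers$protein_to_domains[proteins],
                           use.names = FALSE))
  if (is.null(domains) || !length(domains)) return("NONE")
  di <- layers$interactions
  hit <- di$domain_a %in% domains | di$domain_b %in% domains
  if (!any(hit)) return("NONE")
  .class_from_confidences(di$confidence[hit])
}

.class_from_confidences <- function(conf) {
  conf <- as.integer(factor(as.character(conf),
                            levels = c("EV", "HC", "MC", "LC")))
  n <- length(conf)
  for (k in 1:4) {                     # EV, then EV+HC, ...
    if (sum(conf <= k) / n >= 0.5) return(c("EV", "HC", "MC", "LC")[k])
  }
  "LC"
}

#' Build the full layered structure
#'
#' Connects the SNP universe, SNP-gene map, pathway catalog and
#' protein/domain layers, and computes the interaction class of every gene
#' appearing in the catalog or the SNP-gene map. The result is treated as
#' immutable by the rest of the pipeline.
#'
#' @param snp_ids character vector of SNP ids (the dataset's universe), or a
#'   [genotype_dataset()] from which the universe is taken.
#' @param catalog a `pathway_catalog`.
#' @param snp_gene a `snp_gene_map` built against the same universe.
#' @param layers an [interaction_layers()] object.
#' @return a `layered_structure`: list with `snp_ids`, `catalog`,
#'   `snp_gene`, `layers`, and `gene_class` (named character vector).
#' @export
build_layered_structure <- function(snp_ids, catalog, snp_gene, layers) {
  if (inherits(snp_ids, "genotype_dataset")) snp_ids <- snp_ids$snps$snp_id
  stopifnot(inherits(catalog, "pathway_catalog"),
            inherits(snp_gene, "snp_gene_map"),
            inherits(layers, "interaction_layers"))
  genes <- sort(unique(c(unlist(lapply(catalog, `[[`, "genes"),
                                use.names = FALSE),
                         names(snp_gene$gene_to_snps))))
  gene_class <- vapply(genes, assign_interaction_class, character(1),
                       layers = layers)
  names(gene_class) <- genes
  # pathway membership per gene, for characteristic-set exclusivity
  gene_pathways <- list()
  for (pw in catalog) {
    for (g in pw$genes)
      gene_pathways[[g]] <- c(gene_pathways[[g]], pw$pathway_id)
  }
  structure(list(snp_ids = as.character(snp_ids), catalog = catalog,
                 snp_gene = snp_gene, layers = layers,
                 gene_class = gene_class, gene_pathways = gene_pathways),
            class = "layered_structure")
}

#' @export
print.layered_structure <- function(x, ...) {
  cat("layered_structure:", length(x$snp_ids), "SNPs,",
      length(x$gene_class), "genes,", length(x$catalog), "pathways\n")
  cat("gene interaction classes:\n")
  print(table(factor(x$gene_class, levels = interaction_classes)))
  invisible(x)
}
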