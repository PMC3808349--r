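# Synthetic genotype and annotation generators. Everything the pipeline
# consumes — PLINK triplets, GMT catalogs, the SNP-gene and protein/domain
# tables — can be produced here at small scale with known structure,
# including an implanted associated pathway with a chosen per-SNP allelic
# odds ratio.

#' Simulation configuration
#'
#' @param n_cases,n_controls sample counts (defaults 1000/1000, the scale
#'   of a modest case-control panel).
#' @param n_snps total SNPs; when a structure is supplied to
#'   [simulate_dataset()] and maps fewer SNPs, the remainder are unmapped
#'   filler SNPs (emulating the small fraction of chip SNPs with no gene).
#' @param maf_range interval within (0, 0.5] from which per-SNP minor
#'   allele frequencies are drawn uniformly (default `c(0.1, 0.5)`, common
#'   post-QC chip territory).
#' @param effect_pathway pathway id whose genes' SNPs carry the effect, or
#'   `NULL` for a null simulation.
#' @param odds_ratio per-SNP allelic odds ratio for effect SNPs (default 1
#'   = null).
#' @param missing_rate per-call missing probability (default 0).
#' @param seed RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 1000, n_controls = 1000,
                              n_snps = 500, maf_range = c(0.1, 0.5),
                              effect_pathway = NULL, odds_ratio = 1,
                              missing_rate = 0, seed = NULL) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (odds_ratio <= 0) stop("odds_ratio must be positive")
  base::structure(list(n_cases = n_cases, n_controls = n_controls,
                       n_snps = n_snps, maf_range = maf_range,
                       effect_pathway = effect_pathway,
                       odds_ratio = odds_ratio,
                       missing_rate = missing_rate, seed = seed),
                  class = "simulation_config")
}

# closed-form case allele frequency realizing an allelic odds ratio
# against a control frequency p: OR = [q/(1-q)] / [p/(1-p)].
.case_freq_from_or <- function(p, or) or * p / (1 - p + or * p)

#' Simulate a case/control genotype dataset
#'
#' Control genotypes are drawn per SNP as binomial(2, maf) — i.e. under
#' Hardy-Weinberg equilibrium with independent SNPs. SNPs mapped to genes
#' of `cfg$effect_pathway` (through `structure`) have their case allele
#' frequency tilted to realize the configured allelic odds ratio; all
#' other SNPs are identically distributed in cases and controls.
#'
#' @param cfg a [simulation_config()].
#' @param structure optional [build_layered_structure()] result providing
#'   the SNP universe and the effect pathway's SNPs.
#' @param ld_duplicate_snps optional character vector of SNP ids to emit a
#'   perfectly correlated copy of (id suffixed `_dup`), for exercising
#'   linkage-disequilibrium behaviour of the set statistic.
#' @return a [genotype_dataset()], samples ordered cases first.
#' @export
simulate_dataset <- function(cfg, structure = NULL,
                             ld_duplicate_snps = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (!is.null(structure)) {
    snp_ids <- structure$snp_ids
    if (cfg$n_snps > length(snp_ids))
      snp_ids <- c(snp_ids,
                   sprintf("snp_unmapped_%04d",
                           seq_len(cfg$n_snps - length(snp_ids))))
  } else {
    snp_ids <- sprintf("snp_%05d", seq_len(cfg$n_snps))
  }
  n_snps <- length(snp_ids)
  maf <- stats::runif(n_snps, cfg$maf_range[1], cfg$maf_range[2])

  effect <- rep(FALSE, n_snps)
  if (!is.null(cfg$effect_pathway)) {
    if (is.null(structure))
      stop("effect_pathway requires a layered structure")
    pw <- structure$catalog[[cfg$effect_pathway]]
    if (is.null(pw))
      stop("effect pathway absent from structure: ", cfg$effect_pathway)
    eff_snps <- unique(unlist(
      structure$snp_gene$gene_to_snps[pw$genes], use.names = FALSE))
    effect <- snp_ids %in% eff_snps
  }
  p_ctrl <- maf
  p_case <- ifelse(effect, .case_freq_from_or(maf, cfg$odds_ratio), maf)

  n <- cfg$n_cases + cfg$n_controls
  geno <- matrix(0L, nrow = n, ncol = n_snps)
  for (j in seq_len(n_snps)) {
    geno[, j] <- c(stats::rbinom(cfg$n_cases, 2, p_case[j]),
                   stats::rbinom(cfg$n_controls, 2, p_ctrl[j]))
  }
  if (cfg$missing_rate > 0)
    geno[matrix(stats::runif(length(geno)) < cfg$missing_rate,
                nrow = n)] <- NA_integer_

  snps <- data.frame(snp_id = snp_ids, chrom = "1",
                     pos = 10000L * seq_len(n_snps),
                     allele1 = "A", allele2 = "B",
                     stringsAsFactors = FALSE)
  sample_ids <- c(sprintf("case_%04d", seq_len(cfg$n_cases)),
                  sprintf("ctrl_%04d", seq_len(cfg$n_controls)))
  phenotype <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  ds <- genotype_dataset(geno, snps, sample_ids, phenotype)
  if (!is.null(ld_duplicate_snps)) {
    idx <- match(ld_duplicate_snps, ds$snps$snp_id)
    if (anyNA(idx)) stop("ld_duplicate_snps names unknown SNPs")
    dup_snps <- ds$snps[idx, , drop = FALSE]
    dup_snps$snp_id <- paste0(dup_snps$snp_id, "_dup")
    dup_snps$pos <- dup_snps$pos + 1L
    ds <- genotype_dataset(cbind(ds$genotypes,
                                 ds$genotypes[, idx, drop = FALSE]),
                           rbind(ds$snps, dup_snps),
                           ds$sample_ids, ds$phenotype)
  }
  ds
}

#' Simulate pathway and interaction annotation
#'
#' Builds a pathway catalog whose consecutive pathways share a controllable
#' fraction of genes (exercising the characteristic-set exclusivity logic),
#' draws each gene's interaction class from `class_mix` and realizes it
#' with a minimal protein/domain/interaction triple, and assigns each gene
#' a small number of SNPs.
#'
#' @param n_genes total genes (some may stay outside any pathway).
#' @param n_pathways number of pathways.
#' @param genes_per_pathway genes per pathway.
#' @param overlap_fraction fraction of each pathway's genes shared with the
#'   previous pathway, in `[0, 1)`.
#' @param class_mix named probabilities over `EV`, `HC`, `MC`, `LC`,
#'   `NONE`.
#' @param snps_per_gene integer vector of possible per-gene SNP counts
#'   (default `2:4`).
#' @param seed RNG seed.
#' @return list with `catalog` (a `pathway_catalog`), `snp_gene` (a
#'   `snp_gene_map`), `layers` (an [interaction_layers()]), `snp_ids` and
#'   `gene_class` (the intended class per gene).
#' @export
simulate_annotation <- function(n_genes = 50, n_pathways = 10,
                                genes_per_pathway = 5,
                                overlap_fraction = 0,
                                class_mix = c(EV = 0.25, HC = 0.25,
                                              MC = 0.2, LC = 0.15,
                                              NONE = 0.15),
                                snps_per_gene = 2:4, seed = NULL) {
  if (n_genes < 1 || n_pathways < 1 || genes_per_pathway < 1)
    stop("counts must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_shared <- floor(overlap_fraction * genes_per_pathway)
  n_fresh_total <- genes_per_pathway +
    (n_pathways - 1) * (genes_per_pathway - n_shared)
  if (n_fresh_total > n_genes)
    stop("infeasible: ", n_fresh_total, " distinct genes needed but only ",
         n_genes, " available")
  genes <- sprintf("gene_%04d", seq_len(n_genes))

  sets <- list()
  next_fresh <- 1L
  prev <- character(0)
  for (i in seq_len(n_pathways)) {
    shared <- if (i > 1 && n_shared > 0) utils::tail(prev, n_shared)
              else character(0)
    n_new <- genes_per_pathway - length(shared)
    fresh <- genes[next_fresh:(next_fresh + n_new - 1L)]
    next_fresh <- next_fresh + n_new
    sets[[sprintf("pw_%03d", i)]] <- c(shared, fresh)
    prev <- sets[[sprintf("pw_%03d", i)]]
  }
  catalog <- pathway_catalog(sets)

  cls <- sample(names(class_mix), n_genes, replace = TRUE,
                prob = as.numeric(class_mix))
  names(cls) <- genes
  gp <- pd <- di <- NULL
  for (g in genes[cls != "NONE"]) {
    pr <- paste0("prot_", g); dm <- paste0("dom_", g)
    gp <- rbind(gp, data.frame(gene_id = g, protein_id = pr))
    pd <- rbind(pd, data.frame(protein_id = pr, domain_id = dm))
    di <- rbind(di, data.frame(domain_a = dm,
                               domain_b = paste0("hub_", g),
                               confidence = cls[[g]]))
  }
  if (is.null(gp)) {
    gp <- data.frame(gene_id = character(), protein_id = character())
    pd <- data.frame(protein_id = character(), domain_id = character())
    di <- data.frame(domain_a = character(), domain_b = character(),
                     confidence = character())
  }
  layers <- interaction_layers(gp, pd, di)

  links <- do.call(rbind, lapply(genes, function(g) {
    k <- if (length(snps_per_gene) == 1) snps_per_gene
         else sample(snps_per_gene, 1)
    data.frame(snp_id = sprintf("snp_%s_%02d", g, seq_len(k)),
               gene_id = g,
               relation = sample(c("coding", "upstream", "downstream"), k,
                                 replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  snp_ids <- links$snp_id
  sg <- snp_gene_map(links, snp_ids)
  list(catalog = catalog, snp_gene = sg, layers = layers,
       snp_ids = snp_ids, gene_class = cls)
}

#' Simulate a complete study (annotation + genotypes + structure)
#'
#' @param cfg a [simulation_config()]; its seed drives both the annotation
#'   and the genotypes (annotation uses `seed + 1`).
#' @param ... passed to [simulate_annotation()].
#' @return list with `dataset`, `structure`, `annotation`.
#' @export
simulate_study <- function(cfg, ...) {
  stopifnot(inherits(cfg, "simulation_config"))
  ann_seed <- if (is.null(cfg$seed)) NULL else (cfg$seed %% 2147483046L) + 1L
  ann <- simulate_annotation(..., seed = ann_seed)
  str0 <- build_layered_structure(ann$snp_ids, ann$catalog, ann$snp_gene,
                                  ann$layers)
  ds <- simulate_dataset(cfg, structure = str0)
  structure <- build_layered_structure(ds$snps$snp_id, ann$catalog,
                                       ann$snp_gene, ann$layers)
  list(dataset = ds, structure = structure, annotation = ann)
}

#' Write annotation files to disk
#'
#' Emits the GMT catalog and the four TSV layers in the formats the loaders
#' read, bit-stable for a given annotation.
#'
#' @param ann result of [simulate_annotation()].
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gmt = file.path(dir, "pathways.gmt"),
             snp_gene = file.path(dir, "snp_gene.tsv"),
             gene_protein = file.path(dir, "gene_protein.tsv"),
             protein_domain = file.path(dir, "protein_domain.tsv"),
             domain_interaction = file.path(dir, "domain_interactions.tsv"))
  gmt <- vapply(ann$catalog, function(pw)
    paste(c(pw$pathway_id, pw$name, pw$genes), collapse = "\t"),
    character(1))
  writeLines(gmt, paths["gmt"])
  utils::write.table(ann$snp_gene$links, paths["snp_gene"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gp <- do.call(rbind, lapply(names(ann$layers$gene_to_proteins), function(g)
    data.frame(gene_id = g, protein_id = ann$layers$gene_to_proteins[[g]])))
  if (is.null(gp)) gp <- data.frame(gene_id = character(),
                                    protein_id = character())
  utils::write.table(gp, paths["gene_protein"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pd <- do.call(rbind,
                lapply(names(ann$layers$protein_to_domains), function(p)
    data.frame(protein_id = p,
               domain_id = ann$layers$protein_to_domains[[p]])))
  if (is.null(pd)) pd <- data.frame(protein_id = character(),
                                    domain_id = character())
  utils::write.table(pd, paths["protein_domain"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$layers$interactions, paths["domain_interaction"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Worked pathway-overlap fixture
#'
#' A small deterministic world with three pathways x, y, z: pathway x holds
#' genes g1..g5; g1 (class EV, SNPs s01-s03) also belongs to y and z, so
#' every characteristic variant of x omits s01-s03. g2 is an x-exclusive EV
#' gene, g3 an x-exclusive HC gene, g4 and g5 x-exclusive genes without any
#' domain interaction (class NONE). With deduplication on, x yields exactly
#' six distinct sets: simple, characteristic, two interaction tiers and two
#' characteristic-interaction tiers. Class assignments beyond g1 are a
#' reconstruction consistent with that layout, synthetic by design. A
#' 20-sample null genotype matrix (10 cases, 10 controls) is attached.
#'
#' @return list with `structure` (a `layered_structure`) and `dataset`
#'   (a [genotype_dataset()]).
#' @export
demo_fixture <- function() {
  gene_snps <- list(g1 = c("s01", "s02", "s03"), g2 = c("s04", "s05"),
                    g3 = c("s06", "s07"), g4 = c("s08", "s09"),
                    g5 = c("s10", "s11"), g6 = c("s12", "s13"),
                    g7 = c("s14", "s15"))
  links <- do.call(rbind, lapply(names(gene_snps), function(g)
    data.frame(snp_id = gene_snps[[g]], gene_id = g, relation = "coding",
               stringsAsFactors = FALSE)))
  snp_ids <- links$snp_id
  catalog <- pathway_catalog(list(x = paste0("g", 1:5),
                                  y = c("g1", "g6"),
                                  z = c("g1", "g7")))
  cls <- c(g1 = "EV", g2 = "EV", g3 = "HC", g6 = "MC", g7 = "LC")
  gp <- data.frame(gene_id = names(cls),
                   protein_id = paste0("prot_", names(cls)))
  pd <- data.frame(protein_id = paste0("prot_", names(cls)),
                   domain_id = paste0("dom_", names(cls)))
  di <- data.frame(domain_a = paste0("dom_", names(cls)),
                   domain_b = paste0("hub_", names(cls)),
                   confidence = unname(cls))
  layers <- interaction_layers(gp, pd, di)
  sg <- snp_gene_map(links, snp_ids)
  str <- build_layered_structure(snp_ids, catalog, sg, layers)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  cfg <- simulation_config(n_cases = 10, n_controls = 10,
                           n_snps = length(snp_ids),
                           maf_range = c(0.2, 0.4), seed = 8675309)
  ds <- simulate_dataset(cfg, structure = str)
  list(structure = str, dataset = ds)
}
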