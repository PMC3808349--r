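# Shared fixture builders. Everything is generated in code; nothing binary.

# dataset from an explicit samples x snps dosage matrix
make_dataset <- function(geno, phenotype,
                         snp_ids = sprintf("s%02d", seq_len(ncol(geno)))) {
  snps <- data.frame(snp_id = snp_ids, chrom = "1",
                     pos = seq_len(ncol(geno)) * 1000L,
                     allele1 = "A", allele2 = "B",
                     stringsAsFactors = FALSE)
  genotype_dataset(geno, snps, sprintf("i%03d", seq_len(nrow(geno))),
                   phenotype)
}

# dataset realizing a given 2x2 allele table (cases a1/a2, controls a1/a2)
# via het/hom composition; counts must be even-compatible
dataset_from_allele_table <- function(case_a1, case_a2, ctrl_a1, ctrl_a2) {
  geno_group <- function(n_a1, n_a2) {
    n <- (n_a1 + n_a2) / 2
    stopifnot(n == floor(n))
    # use hets as far as possible, then homs
    n_het <- min(n_a1, n_a2)
    if ((n_a1 - n_het) %% 2 != 0) n_het <- n_het - 1
    n_hom1 <- (n_a1 - n_het) / 2
    n_hom2 <- n - n_het - n_hom1
    c(rep(2L, n_hom1), rep(1L, n_het), rep(0L, n_hom2))
  }
  g <- c(geno_group(case_a1, case_a2), geno_group(ctrl_a1, ctrl_a2))
  n_case <- (case_a1 + case_a2) / 2
  make_dataset(matrix(g, ncol = 1),
               c(rep("case", n_case), rep("control", length(g) - n_case)))
}

# minimal interaction layers giving one gene a pooled multiset of
# interaction confidences
layers_with_confidences <- function(confidences, gene = "g1") {
  gp <- data.frame(gene_id = gene, protein_id = "p1")
  pd <- data.frame(protein_id = "p1", domain_id = "d1")
  di <- data.frame(domain_a = "d1",
                   domain_b = sprintf("h%02d", seq_along(confidences)),
                   confidence = confidences)
  interaction_layers(gp, pd, di)
}

# small study used by several pipeline tests
small_study <- function(seed = 1, n_cases = 60, n_controls = 60,
                        effect_pathway = NULL, odds_ratio = 1,
                        n_pathways = 4, overlap_fraction = 0.2) {
  cfg <- simulation_config(n_cases = n_cases, n_controls = n_controls,
                           n_snps = 1, effect_pathway = effect_pathway,
                           odds_ratio = odds_ratio, seed = seed)
  simulate_study(cfg, n_genes = 5 * n_pathways, n_pathways = n_pathways,
                 genes_per_pathway = 5, overlap_fraction = overlap_fraction,
                 snps_per_gene = 2:3)
}
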