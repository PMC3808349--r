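Package: mipgwas
Title: Multistage Integrative Pathway Analysis for Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("MIP", "Maintainers", email = "maintainers@mipgwas.example.org",
           role = c("aut", "cre"))
Description: Pathway-based analysis of case-control genome-wide association
    studies that layers SNP, gene, protein, domain-interaction and pathway
    annotation into a single structure, derives four families of
    pathway-based SNP sets (simple, characteristic, interaction tiers, and
    characteristic-interaction tiers), scores each set with a permutation
    variant of Fisher's combined probability statistic, and runs a
    multistage sensitivity analysis that excludes top-ranking SNPs to find
    pathways whose significance does not hinge on a handful of markers.
    Includes PLINK bed/bim/fam input and output, standard genotype quality
    control, and a synthetic-data generator for fully self-contained
    testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
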