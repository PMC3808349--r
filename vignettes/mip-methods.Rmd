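---
title: "Multistage integrative pathway analysis: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage integrative pathway analysis: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipgwas)
```

## The problem

Single-marker GWAS statistics miss risk variants of small effect. If risk
alleles cluster in functionally related genes, testing *SNP sets defined by
pathways* can recover signal that no individual marker carries. Two things
complicate naive pathway testing: genes shared among several pathways blur
which pathway carries the signal, and pathway databases ignore
protein-interaction evidence that links genes more finely than pathway
membership does. A third problem is specific to the statistics: a pathway
can look associated only because one or two of its SNPs are extreme.

`mipgwas` addresses all three. It builds a five-layer data structure
(SNPs, genes, proteins, domain interactions, pathways), derives four
families of pathway SNP sets from it, scores each set with a permutation
version of Fisher's combined probability statistic, and repeats the whole
analysis after excluding top-ranking SNPs at three thresholds. Only
pathways significant in *all* runs are reported as robust.

## The layered structure and the interaction class

Each SNP maps to zero or more genes through a chip-annotation table
(`coding`, `upstream`, `downstream` relations are all accepted; SNPs absent
from the table stay unmapped and never enter a set). Each gene maps to
proteins, each protein to domains, and domains carry an undirected
interaction list labelled with a confidence category: `EV`
(experimentally validated), `HC`, `MC`, `LC` in descending confidence — the
convention of domain-interaction databases.

A gene's **interaction class** is the median confidence of all
domain-domain interactions touching any of its domains: the most confident
class `c` such that at least 50% (inclusive) of the pooled interactions
have confidence `c` or better. Two choices here are ours, because the
convention leaves them open:

* interactions are pooled **once per unordered domain pair** regardless of
  how many of the gene's domains they touch — otherwise a single
  promiscuous pair would dominate the median;
* genes with no proteins, no domains or no interactions get the class
  `NONE`: they are excluded from every interaction-tier set but kept in
  simple/characteristic sets, which is the only reading under which a
  pathway with class-less genes still produces the plain set families.

## The four set families

For a pathway *P* with gene set *G(P)*:

| family | genes used |
|---|---|
| simple | all of *G(P)* |
| characteristic | genes of *G(P)* in no other catalog pathway |
| interaction (ultra/high/medium/low) | genes of class in {EV}, {EV,HC}, {EV,HC,MC}, {EV,HC,MC,LC} |
| characteristic-interaction (4 tiers) | both filters at once |

The SNP set is always the union of the member genes' mapped SNPs. The tier
sets nest (`ultra ⊆ high ⊆ medium ⊆ low ⊆ simple`), the low tier is the
superset of every interaction tier, and each characteristic variant nests
in its counterpart; the test suite asserts these invariants over
randomized annotations.

Two defaults shape the output and are deliberate:

* **Deduplication is on.** Tier definitions frequently coincide (for
  example when a pathway has no `MC`/`LC` genes, medium = high). We keep
  one representative per distinct SNP set, labelled with the
  least-restrictive definition that produced it (simple, then
  characteristic, then interaction low→ultra, then
  characteristic-interaction low→ultra). In the worked overlap fixture
  (`demo_fixture()`) this turns the ten candidate constructions into the
  six materially different sets. `dedup = FALSE` recovers the literal ten.
* **Minimum set size is 2 SNPs.** A single-SNP "pathway set" is a
  single-marker test in disguise and contradicts the purpose of set
  testing; undersized sets are dropped.

## The set statistic

Given per-SNP allelic p-values (1-df Pearson chi-square on the 2×2
allele-count table, no continuity correction — the basic single-marker
test of standard GWAS toolkits), a set's statistic is Fisher's
combination

$$T = \sum_{i \in \text{set}} -2 \ln p_i .$$

Significance comes from a permutation null: case/control labels are
shuffled jointly across samples (preserving the case count), per-SNP
p-values are recomputed for the set's SNPs, and the set p-value is

$$p = \frac{r + 1}{B + 1}, \qquad r = \#\{b : T^{(b)} \ge T_{\text{obs}}\},$$

with `B = 5000` permutations by default (more did not change results in
our calibration runs, and the add-one estimator never reports zero).
Choices worth stating:

* **Label permutation, not SNP resampling.** Only permuting phenotype
  labels preserves the linkage disequilibrium among a set's SNPs under
  the null; a duplicated-SNP fixture in the test suite confirms that a
  perfectly correlated pair behaves exactly like a doubled single SNP.
* **Ties count as exceedances** (conservative); an all-monomorphic set
  yields p = 1, not 1/(B+1).
* **Shared permutations are on by default**: one label stream per run,
  reused by every set. This makes set p-values comparable within a run
  and lets the per-permutation SNP statistics be computed once over the
  union of all set SNPs. Per-set independent streams are a flag away.
* **Resolution floor.** With B permutations the smallest reportable value
  is 1/(B+1); zero-exceedance results are displayed as `<=` that floor
  rather than as a point estimate.
* Per-SNP p-values are clamped at 1e-300 before the log so `T` stays
  finite; monomorphic SNPs and SNPs with an empty phenotype group carry
  p = 1 (zero information) by convention.

An independent oracle, `exact_permutation_pvalue()`, enumerates every
distinct label arrangement with plain loops and the textbook chi-square
formula; on small fixtures the vectorised scorer in exhaustive mode must
match it exactly, and does in the acceptance suite.

## The multistage procedure

Stage 1 scores all sets on the full QC'd SNP universe. Stages 2–4 first
remove every SNP whose *observed* single-marker p-value is strictly below
1e-3, 1e-4, 1e-5 respectively, rebuild all sets on the surviving universe,
and re-score. Exclusion is a pre-processing of each stage: permutations
never re-decide membership. Per stage, a **best list** keeps at most one
set per pathway — the minimal-p set, admitted only if p ≤ 0.05 (ties
broken by larger SNP count, then family precedence, then lexically;
determinism is non-negotiable). Pathways present in every stage's best
list are the **consistently significant** ones; a pathway whose
significance rested on one extreme marker loses it the moment that marker
is excluded, which is precisely the failure mode the stages detect. The
method attribution summarises which set family won the best-list entries,
separating the interaction-informed families from the plain ones.

Seeding is hierarchical: the master seed generates one sub-seed per stage
(a single `sample.int` draw each, in stage order), and the stage seed
drives a permutation stream that depends only on the sample count — so
enlarging the pathway catalog never perturbs existing pathways' results.

## Quality control

Filters run in a fixed order so reports are deterministic: sample
missingness (> 5% removed), SNP missingness (> 5%), minor allele
frequency (< 5%), then an exact Hardy-Weinberg test (Wigginton-style,
two-sided by probability mass) in controls at `hwe_alpha = 1e-3`. The HWE
filter is applied to SNPs in controls — the standard practice — and the
threshold is configurable because conventions differ between studies.
Missing genotypes are dropped per SNP (complete-case allele counting); no
imputation is attempted.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` draws control genotypes per SNP as binomial(2, MAF)
— Hardy-Weinberg proportions, independent SNPs — with MAF uniform on
[0.1, 0.5] by default (post-QC chip territory). An associated pathway is
implanted by tilting the case allele frequency to realize a chosen
allelic odds ratio in closed form
(`q = OR·p / (1 − p + OR·p)`); no liability-threshold model is used.
`simulate_annotation()` builds a pathway catalog with controllable
gene overlap between consecutive pathways, draws gene classes from a
configurable mix, and realizes each class with a minimal
protein/domain/interaction triple.

What this world does **not** contain: linkage disequilibrium (except an
optional exact-duplicate mode used to test LD handling), population
structure, genotyping batch effects, realistic pathway size distributions
or hub genes shared among many pathways. A green test therefore
establishes the statistical machinery — calibration, power against the
stated alternative, stage behaviour, determinism — not performance on any
real cohort.

Default simulation sizes used by the acceptance suite (chosen once, as a
plausible desk-scale study): null calibration at 100+100 samples,
500 SNPs, 10 pathways, 500 permutations, 200 replicates; power at
1000+1000 samples, an odds ratio of 1.3 on a 20-SNP pathway, 1000
permutations, 50 replicates.

## Numerical and degenerate-input choices

* Allele-table chi-square with any zero margin → statistic 0, p = 1.
* HWE exact test on a monomorphic SNP → p = 1 (single possible table);
  all-zero counts are an error.
* Phenotype codes 0/−9 in a `.fam` drop the sample with a warning; any
  other code is an error.
* QC that removes every sample or every SNP raises rather than returning
  an empty dataset.
* `best_list` and the set dump are sorted and fully tie-broken, so equal
  seeds give byte-identical serialized reports.

## Known limitations

* The allelic test assumes the 2×2 chi-square approximation per SNP; very
  rare alleles surviving QC could strain it (permutation calibration of
  `T` does not depend on it, only the ranking within a permutation does).
* With 5000 permutations the floor is 2×10⁻⁴; genuinely smaller set
  p-values are reported as `<=` the floor, not resolved.
* Covariates, relatedness and sex chromosomes are out of scope; inputs
  are expected to be pre-cleaned case/control autosomal genotypes.
* Exclusivity for characteristic sets is judged against the loaded
  catalog only: a gene absent from the catalog's other pathways counts as
  exclusive even if some unloaded database lists it elsewhere.
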