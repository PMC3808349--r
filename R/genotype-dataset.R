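#' Construct a case/control genotype dataset
#'
#' The SNP layer of the analysis: a samples-by-SNPs matrix of allele-1 dosages
#' (0, 1, 2 or `NA` for a missing call) together with SNP metadata and a
#' case/control phenotype.
#'
#' @param genotypes integer matrix, samples in rows and SNPs in columns;
#'   entries count copies of `allele1` and missing calls are `NA`.
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`, `allele1`,
#'   `allele2`; one row per column of `genotypes`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param phenotype factor or character vector with levels `"control"` and
#'   `"case"`, one entry per sample.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `snps`, `sample_ids`, `phenotype`.
#' @export
genotype_dataset <- function(genotypes, snps, sample_ids, phenotype) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  needed <- c("snp_id", "chrom", "pos", "allele1", "allele2")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols))
    stop("snps table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("snp_id values must be unique")
  if (any(snps$pos < 1L))
    stop("SNP positions must be 1-based (pos >= 1)")
  if (nrow(snps) != ncol(genotypes))
    stop("snps table has ", nrow(snps), " rows but genotype matrix has ",
         ncol(genotypes), " columns")
  if (length(sample_ids) != nrow(genotypes))
    stop("sample_ids length does not match genotype matrix rows")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  phenotype <- factor(as.character(phenotype), levels = c("control", "case"))
  if (length(phenotype) != length(sample_ids))
    stop("phenotype must be defined for every sample")
  if (anyNA(phenotype))
    stop("phenotype entries must be 'case' or 'control'")
  if (any(!is.na(genotypes) & (genotypes < 0L | genotypes > 2L)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  dimnames(genotypes) <- list(sample_ids, snps$snp_id)
  structure(
    list(genotypes = genotypes, snps = snps,
         sample_ids = as.character(sample_ids), phenotype = phenotype),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  tab <- table(x$phenotype)
  cat("genotype_dataset: ", length(x$sample_ids), " samples (",
      tab[["case"]], " cases / ", tab[["control"]], " controls), ",
      nrow(x$snps), " SNPs\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missing call rate: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples and SNPs
#' @param ds a `genotype_dataset`
#' @return integer vector `c(samples, snps)`
#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset
#'
#' @param ds a `genotype_dataset`
#' @param samples index (logical, integer or character) into samples, or
#'   `NULL` to keep all.
#' @param snps index into SNPs, or `NULL` to keep all.
#' @return a `genotype_dataset` restricted to the selection.
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(samples)) seq_along(ds$sample_ids) else samples
  vi <- if (is.null(snps)) seq_len(nrow(ds$snps)) else snps
  g <- ds$genotypes[si, vi, drop = FALSE]
  genotype_dataset(g, ds$snps[vi, , drop = FALSE],
                   ds$sample_ids[si], ds$phenotype[si])
}
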