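# PLINK 1.x binary I/O. The bed format stores genotypes SNP-major, two bits
# per sample, four samples per byte, low-order bits first:
#   00 -> homozygous allele1 (dosage 2)
#   01 -> missing
#   10 -> heterozygous (dosage 1)
#   11 -> homozygous allele2 (dosage 0)
# Magic bytes 0x6c 0x1b, then 0x01 for SNP-major mode.

.plink_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: dosage of allele1 for each 2-bit field of a byte value.
.bed_decode_table <- local({
  two_bit <- c(2L, NA_integer_, 1L, 0L)  # indexed by code 00,01,10,11
  tab <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1L, k] <- two_bit[(v %% 4L) + 1L]
      v <- v %/% 4L
    }
  }
  tab
})

.bed_encode_code <- function(dosage) {
  # inverse of the decode map, dosage -> 2-bit code
  code <- integer(length(dosage))
  code[is.na(dosage)] <- 1L
  code[!is.na(dosage) & dosage == 2L] <- 0L
  code[!is.na(dosage) & dosage == 1L] <- 2L
  code[!is.na(dosage) & dosage == 0L] <- 3L
  code
}

#' Read a PLINK 1.x bed/bim/fam dataset
#'
#' Decodes the SNP-major binary genotype format used by PLINK 1.x. Phenotype
#' code 1 is interpreted as control, 2 as case; samples with code 0 or -9
#' (missing) are dropped with a warning.
#'
#' @param bed_path path to the `.bed` binary genotype file.
#' @param bim_path path to the `.bim` SNP table (six columns: chromosome,
#'   SNP id, genetic distance, 1-based position, allele1, allele2).
#' @param fam_path path to the `.fam` sample table (six columns: family id,
#'   individual id, paternal id, maternal id, sex, phenotype).
#' @return a [genotype_dataset()] with dosages counting copies of allele1
#'   (the `.bim` A1 allele).
#' @export
read_plink <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(bim_path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pid", "mid", "sex",
                                         "pheno"))
  n_samples <- nrow(fam)
  n_snps <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:3], .plink_magic))
    stop("not a PLINK 1.x SNP-major bed file (bad magic bytes): ", bed_path)
  bytes_per_snp <- ceiling(n_samples / 4)
  expected <- 3L + bytes_per_snp * n_snps
  if (length(raw) != expected)
    stop("bed size (", length(raw), " bytes) inconsistent with bim/fam ",
         "dimensions (expected ", expected, " bytes)")

  body <- as.integer(raw[-(1:3)])
  # decode whole file at once: rows = byte index, 4 dosage slots per byte
  dos <- .bed_decode_table[body + 1L, , drop = FALSE]
  dos <- matrix(t(dos), nrow = bytes_per_snp * 4L, ncol = n_snps)
  geno <- dos[seq_len(n_samples), , drop = FALSE]  # samples x snps

  bad <- !(fam$pheno %in% c(0, -9, 1, 2))
  if (any(bad))
    stop("phenotype codes outside {1, 2, 0, -9} in fam file: ",
         paste(unique(fam$pheno[bad]), collapse = ", "))
  drop <- fam$pheno %in% c(0, -9)
  if (any(drop)) {
    warning(sum(drop), " sample(s) with missing phenotype (0/-9) dropped")
    fam <- fam[!drop, , drop = FALSE]
    geno <- geno[!drop, , drop = FALSE]
  }
  if (nrow(fam) == 0L) stop("no samples with a usable phenotype remain")
  phenotype <- ifelse(fam$pheno == 2, "case", "control")
  sample_ids <- if (anyDuplicated(fam$iid)) paste(fam$fid, fam$iid, sep = "_")
                else fam$iid
  genotype_dataset(geno, bim[, c("snp_id", "chrom", "pos",
                                 "allele1", "allele2")],
                   sample_ids, phenotype)
}

#' Write a dataset as PLINK bed/bim/fam
#'
#' @param ds a [genotype_dataset()].
#' @param prefix path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n_samples <- length(ds$sample_ids)
  n_snps <- nrow(ds$snps)
  bytes_per_snp <- ceiling(n_samples / 4)

  codes <- .bed_encode_code(ds$genotypes)        # samples x snps, by column
  codes <- matrix(codes, nrow = n_samples)
  pad <- bytes_per_snp * 4L - n_samples
  if (pad > 0L)
    codes <- rbind(codes, matrix(3L, nrow = pad, ncol = n_snps))
  # pack 4 two-bit codes per byte, low-order bits = first sample
  idx <- seq(1L, nrow(codes), by = 4L)
  bytes <- codes[idx, , drop = FALSE] +
    4L * codes[idx + 1L, , drop = FALSE] +
    16L * codes[idx + 2L, , drop = FALSE] +
    64L * codes[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.plink_magic, con)
  writeBin(as.raw(bytes), con)

  bim <- data.frame(chrom = ds$snps$chrom, snp_id = ds$snps$snp_id, cm = 0,
                    pos = ds$snps$pos, allele1 = ds$snps$allele1,
                    allele2 = ds$snps$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = ds$sample_ids, iid = ds$sample_ids, pid = 0, mid = 0,
                    sex = 0, pheno = ifelse(ds$phenotype == "case", 2L, 1L))
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
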