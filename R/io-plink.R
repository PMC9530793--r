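#' Genotype matrix container
#'
#' Per-individual biallelic SNP calls coded 0/1/2 (copies of the A1 allele)
#' with `NA` for missing, plus per-SNP metadata. This is the object the QC
#' and kernel functions consume.
#'
#' @param calls integer matrix, individuals in rows, SNPs in columns;
#'   values in `{0, 1, 2, NA}`.
#' @param individual_ids character vector, unique, one per row.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele1`,
#'   `allele2`; `snp_id` unique, one row per column of `calls`.
#' @return An object of class `holo_geno`.
#' @export
geno_matrix <- function(calls, individual_ids, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (anyDuplicated(individual_ids))
    stop_hologreml("duplicate individual ids", "hologreml_validation_error")
  if (anyDuplicated(snps$snp_id))
    stop_hologreml("duplicate SNP ids", "hologreml_validation_error")
  if (nrow(calls) != length(individual_ids) || ncol(calls) != nrow(snps))
    stop_hologreml("calls dimensions do not match id lists",
                   "hologreml_validation_error")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop_hologreml("non-missing calls must be 0, 1 or 2",
                   "hologreml_validation_error")
  dimnames(calls) <- list(individual_ids, snps$snp_id)
  structure(list(calls = calls,
                 individual_ids = as.character(individual_ids),
                 snps = snps),
            class = "holo_geno")
}

#' @export
print.holo_geno <- function(x, ...) {
  cat(sprintf("<holo_geno> %d individuals x %d SNPs, %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.holo_geno <- function(x) dim(x$calls)

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 2-bit code -> call, A1 counted: 00 -> 2 copies of A1, 01 -> missing,
# 10 -> het, 11 -> 0 copies (hom A2). PLINK 1.9 default counting.
BED_DECODE <- c(2L, NA_integer_, 1L, 0L)
BED_ENCODE <- c(`2` = 0L, `1` = 2L, `0` = 3L)   # missing -> 1 handled inline

#' Read PLINK 1 binary genotypes
#'
#' Reads a bed/bim/fam triple in SNP-major mode into a [geno_matrix()].
#' The A1 allele of the bim file is the counted allele: a call of 2 means
#' two copies of A1.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#'   Alternatively pass the three paths explicitly.
#' @param bed_path,bim_path,fam_path explicit file paths (override `prefix`).
#' @return A `holo_geno`.
#' @export
read_plink <- function(prefix = NULL, bed_path = NULL, bim_path = NULL,
                       fam_path = NULL) {
  if (!is.null(prefix)) {
    bed_path <- bed_path %||% paste0(prefix, ".bed")
    bim_path <- bim_path %||% paste0(prefix, ".bim")
    fam_path <- fam_path %||% paste0(prefix, ".fam")
  }
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p))
      stop_hologreml(paste0("file not found: ", p), "hologreml_io_error")

  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character",
                                          "character", "integer",
                                          "character", "character"))
  n_ind <- nrow(fam)
  n_snp <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:3], PLINK_MAGIC))
    stop_hologreml("not a PLINK 1 bed file (bad magic bytes)",
                   "hologreml_format_error")
  bytes_per_snp <- ceiling(n_ind / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * n_snp)
    stop_hologreml(
      sprintf("bed payload is %d bytes, expected %d (%d SNPs x %d bytes)",
              length(body), bytes_per_snp * n_snp, n_snp, bytes_per_snp),
      "hologreml_length_error")

  # each byte packs 4 individuals, LSB pair first
  codes <- matrix(as.integer(body), nrow = bytes_per_snp)
  calls <- matrix(NA_integer_, nrow = n_ind, ncol = n_snp)
  for (k in 0:3) {
    rows <- seq_len(bytes_per_snp) * 4L - 3L + k
    keep <- rows <= n_ind
    two_bit <- codes %/% 4L^k %% 4L
    calls[rows[keep], ] <- BED_DECODE[two_bit[keep, , drop = FALSE] + 1L]
  }

  geno_matrix(calls,
              individual_ids = fam[[2]],
              snps = data.frame(snp_id = bim$snp_id, chrom = bim$chrom,
                                pos = bim$pos, allele1 = bim$allele1,
                                allele2 = bim$allele2,
                                stringsAsFactors = FALSE))
}

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [read_plink()]; SNP-major bed with the standard magic bytes.
#'
#' @param geno a `holo_geno`.
#' @param prefix output path prefix (directory must exist).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  calls <- geno$calls
  n_ind <- nrow(calls)
  n_snp <- ncol(calls)
  bytes_per_snp <- ceiling(n_ind / 4)

  # call -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(1L, nrow = n_ind, ncol = n_snp)
  ok <- !is.na(calls)
  code[ok] <- BED_ENCODE[as.character(calls[ok])]
  pad <- bytes_per_snp * 4L - n_ind
  if (pad > 0) code <- rbind(code, matrix(0L, pad, n_snp))
  weights <- 4L^(0:3)
  byte_mat <- matrix(0L, bytes_per_snp, n_snp)
  for (k in 0:3)
    byte_mat <- byte_mat + weights[k + 1L] *
      code[seq_len(bytes_per_snp) * 4L - 3L + k, , drop = FALSE]

  writeBin(c(PLINK_MAGIC, as.raw(byte_mat)), paste0(prefix, ".bed"))
  s <- geno$snps
  utils::write.table(
    data.frame(s$chrom, s$snp_id, 0, s$pos, s$allele1, s$allele2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- geno$individual_ids
  utils::write.table(
    data.frame(ids, ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
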