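#' Read a phenotype/covariate table
#'
#' TSV with a header; the individual-id column is `IID`. All other columns
#' are kept as-is: numeric traits/covariates stay numeric, `sex` (or any
#' non-numeric column) becomes a factor. Missing cells stay `NA`; model
#' fits drop incomplete rows per model (complete-case) and report how many.
#'
#' @param path TSV path.
#' @return data.frame with attribute-free columns and unique `IID`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path))
    stop_hologreml(paste0("file not found: ", path), "hologreml_io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"IID" %in% names(df))
    stop_hologreml("phenotype table must have an IID column",
                   "hologreml_validation_error")
  df$IID <- as.character(df$IID)
  if (anyDuplicated(df$IID))
    stop_hologreml("duplicate IID in phenotype table",
                   "hologreml_validation_error")
  for (nm in setdiff(names(df), "IID"))
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  df
}

#' Relationship kernel container
#'
#' A symmetric individual-by-individual similarity matrix with ids and a
#' kind tag; the covariance structure of one random effect in the mixed
#' models fitted by [reml_fit()].
#'
#' @param K symmetric numeric matrix.
#' @param ids character vector of individual ids, in matrix order.
#' @param kind one of `"GRM"`, `"MRM"`, `"INTERACTION"`, `"CUSTOM"`.
#' @return An object of class `holo_kernel`.
#' @export
kernel_matrix <- function(K, ids, kind = c("CUSTOM", "GRM", "MRM",
                                           "INTERACTION")) {
  kind <- match.arg(kind)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K) || nrow(K) != length(ids))
    stop_hologreml("kernel dimensions do not match ids",
                   "hologreml_validation_error")
  if (anyDuplicated(ids))
    stop_hologreml("duplicate ids in kernel", "hologreml_validation_error")
  if (!all(is.finite(K)))
    stop_hologreml("non-finite kernel entries", "hologreml_validation_error")
  if (max(abs(K - t(K))) > 1e-10)
    stop_hologreml("kernel not symmetric within 1e-10",
                   "hologreml_validation_error")
  K <- (K + t(K)) / 2
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = as.character(ids), kind = kind,
                 mean_diag = mean(diag(K)), standardized = FALSE),
            class = "holo_kernel")
}

#' @export
print.holo_kernel <- function(x, ...) {
  cat(sprintf("<holo_kernel %s> %d x %d, mean diagonal %.4f%s\n",
              x$kind, nrow(x$K), ncol(x$K), mean(diag(x$K)),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Write a kernel to disk
#'
#' `gcta_bin` dialect: `<prefix>.grm.bin` holds the lower triangle
#' (diagonal included) in row order as little-endian float32, and
#' `<prefix>.grm.id` holds FID/IID pairs, one per line — the layout used by
#' GCTA's `--make-grm`. `tsv` dialect: a square matrix with ids as header
#' and rownames.
#'
#' @param kernel a `holo_kernel`.
#' @param prefix output path prefix (gcta_bin) or file path (tsv).
#' @param dialect `"gcta_bin"` or `"tsv"`.
#' @return `prefix`, invisibly.
#' @export
write_kernel <- function(kernel, prefix, dialect = c("gcta_bin", "tsv")) {
  dialect <- match.arg(dialect)
  K <- kernel$K
  n <- nrow(K)
  if (dialect == "tsv") {
    df <- data.frame(IID = kernel$ids, K, check.names = FALSE)
    colnames(df) <- c("IID", kernel$ids)
    utils::write.table(df, prefix, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(prefix))
  }
  # lower triangle in row order (GCTA layout), diagonal included
  vals <- unlist(lapply(seq_len(n), function(i) K[i, seq_len(i)]),
                 use.names = FALSE)
  writeBin(as.numeric(vals), paste0(prefix, ".grm.bin"), size = 4,
           endian = "little")
  utils::write.table(data.frame(kernel$ids, kernel$ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a kernel from disk
#'
#' Inverse of [write_kernel()]; see that function for the dialects.
#'
#' @param prefix path prefix (gcta_bin) or file path (tsv).
#' @param dialect `"gcta_bin"` or `"tsv"`.
#' @param kind kind tag for the returned kernel.
#' @return A `holo_kernel`.
#' @export
read_kernel <- function(prefix, dialect = c("gcta_bin", "tsv"),
                        kind = "CUSTOM") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.table(prefix, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    K <- as.matrix(df[, -1, drop = FALSE])
    return(kernel_matrix(K, ids, kind))
  }
  id_path <- paste0(prefix, ".grm.id")
  bin_path <- paste0(prefix, ".grm.bin")
  for (p in c(id_path, bin_path))
    if (!file.exists(p))
      stop_hologreml(paste0("file not found: ", p), "hologreml_io_error")
  ids <- utils::read.table(id_path, header = FALSE,
                           colClasses = "character")[[2]]
  n <- length(ids)
  n_vals <- n * (n + 1) / 2
  vals <- readBin(bin_path, what = "numeric", n = n_vals + 1, size = 4,
                  endian = "little")
  if (length(vals) != n_vals)
    stop_hologreml(
      sprintf("grm.bin holds %d values, expected %d for %d ids",
              length(vals), n_vals, n),
      "hologreml_validation_error")
  K <- matrix(0, n, n)
  pos <- 1L
  for (i in seq_len(n)) {
    K[i, seq_len(i)] <- vals[pos:(pos + i - 1L)]
    pos <- pos + i
  }
  K <- K + t(K) - diag(diag(K))
  kernel_matrix(K, ids, kind)
}

#' Harmonize ids across genotype, microbiome and phenotype inputs
#'
#' Restricts all inputs to the individuals present in every one of them,
#' in a canonical (sorted) order so that downstream estimates do not depend
#' on file row order.
#'
#' @param geno a `holo_geno` or NULL.
#' @param otu a `holo_otu` or NULL.
#' @param pheno a phenotype data.frame (with `IID`) or NULL.
#' @return list with the harmonized objects and the common `ids`.
#' @export
harmonize_ids <- function(geno = NULL, otu = NULL, pheno = NULL) {
  sets <- list()
  if (!is.null(geno)) sets <- c(sets, list(geno$individual_ids))
  if (!is.null(otu)) sets <- c(sets, list(otu$individual_ids))
  if (!is.null(pheno)) sets <- c(sets, list(pheno$IID))
  if (!length(sets))
    stop_hologreml("nothing to harmonize", "hologreml_validation_error")
  ids <- sort(Reduce(intersect, sets))
  if (!length(ids))
    stop_hologreml("no individuals shared across inputs",
                   "hologreml_validation_error")
  out <- list(ids = ids)
  if (!is.null(geno)) {
    keep <- match(ids, geno$individual_ids)
    out$geno <- geno_matrix(geno$calls[keep, , drop = FALSE], ids, geno$snps)
  }
  if (!is.null(otu)) {
    keep <- match(ids, otu$individual_ids)
    out$otu <- otu_abundance(otu$abundance[, keep, drop = FALSE],
                             otu$otu_ids, ids, otu$taxonomy,
                             counts = if (!is.null(otu$counts))
                               otu$counts[, keep, drop = FALSE])
  }
  if (!is.null(pheno)) out$pheno <- pheno[match(ids, pheno$IID), ,
                                          drop = FALSE]
  out
}
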