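#' Build the genomic relationship matrix
#'
#' Two standard dialects over QC'd genotypes, both using the coded-allele
#' frequencies `p_i` (in-sample by default, via [allele_stats()]):
#'
#' * `vanraden`: `G = Z Z' / (2 sum_i p_i (1 - p_i))` with
#'   `Z = calls - 2 p` columnwise — a single genome-wide denominator.
#' * `gcta`: `g_jk = (1/N) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#'   (2 p_i (1 - p_i))` — each SNP standardized to unit variance before
#'   averaging.
#'
#' Missing calls are mean-imputed to `2 p_i` (so they contribute zero after
#' centering). With in-sample frequencies every row of either G sums to
#' zero. SNPs with `p` of 0 or 1 must be removed by QC first.
#'
#' @param geno a `holo_geno` (after [qc_filter()]).
#' @param stats optional [allele_stats()] output (recomputed if omitted).
#' @param dialect `"vanraden"` (default) or `"gcta"`.
#' @return a `holo_kernel` of kind `"GRM"`.
#' @export
build_grm <- function(geno, stats = NULL, dialect = c("vanraden", "gcta")) {
  dialect <- match.arg(dialect)
  if (is.null(stats)) stats <- allele_stats(geno)
  p <- stats$p
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop_hologreml(
      "monomorphic or undefined SNPs present; run qc_filter first",
      "hologreml_validation_error")
  Z <- sweep(geno$calls, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0                    # mean imputation: 2p - 2p = 0
  G <- if (dialect == "vanraden") {
    tcrossprod(Z) / (2 * sum(p * (1 - p)))
  } else {
    Zs <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    tcrossprod(Zs) / ncol(Z)
  }
  kernel_matrix(G, geno$individual_ids, "GRM")
}

#' Hadamard interaction kernel
#'
#' The elementwise (Schur) product `A_ij = G_ij * M_ij` of a genomic and a
#' microbial kernel, the covariance structure of the host-genetics x
#' microbiome interaction random effect. By the Schur product theorem A is
#' positive semi-definite whenever both inputs are.
#'
#' @param g,m `holo_kernel`s over the same ids in the same order.
#' @return a `holo_kernel` of kind `"INTERACTION"`.
#' @export
interaction_kernel <- function(g, m) {
  if (!identical(g$ids, m$ids))
    stop_hologreml("kernels have different ids or orders",
                   "hologreml_validation_error")
  kernel_matrix(g$K * m$K, g$ids, "INTERACTION")
}

#' Standardize a kernel to mean diagonal 1
#'
#' Divides the matrix by its mean diagonal so that the variance component
#' attached to each kernel is on the same (phenotypic-variance) scale and
#' the fitted fractions are directly comparable across kernels.
#'
#' @param kernel a `holo_kernel` with positive mean diagonal.
#' @return the rescaled `holo_kernel` (`standardized = TRUE`; the original
#'   mean diagonal is kept in `mean_diag_raw`).
#' @export
standardize_kernel <- function(kernel) {
  md <- mean(diag(kernel$K))
  if (!is.finite(md) || md <= 0)
    stop_hologreml("kernel mean diagonal must be positive",
                   "hologreml_validation_error")
  out <- kernel_matrix(kernel$K / md, kernel$ids, kernel$kind)
  out$standardized <- TRUE
  out$mean_diag_raw <- md
  out
}

#' Principal components from a kernel
#'
#' Eigen-decomposes the kernel and returns the leading eigenvectors scaled
#' by the square root of their eigenvalues, ordered by decreasing
#' eigenvalue. GRM/MRM/INTERACTION kernels built with in-sample
#' frequencies are already column-centered and are used as-is; CUSTOM
#' kernels are double-centered first. Sign convention: within each PC the
#' loading of largest magnitude is positive.
#'
#' @param kernel a `holo_kernel`.
#' @param n_pcs number of components (at most n).
#' @return n x n_pcs matrix, rownames = ids, colnames PC1..PCk.
#' @export
kernel_pca <- function(kernel, n_pcs) {
  K <- kernel$K
  n <- nrow(K)
  if (n_pcs > n)
    stop_hologreml("n_pcs exceeds the number of individuals",
                   "hologreml_validation_error")
  if (kernel$kind == "CUSTOM") {
    J <- diag(n) - matrix(1 / n, n, n)
    K <- J %*% K %*% J
  }
  eig <- eigen(K, symmetric = TRUE)
  vals <- pmax(eig$values[seq_len(n_pcs)], 0)
  pcs <- eig$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(vals), n_pcs)
  for (j in seq_len(n_pcs)) {
    i_max <- which.max(abs(pcs[, j]))
    if (pcs[i_max, j] < 0) pcs[, j] <- -pcs[, j]
  }
  dimnames(pcs) <- list(kernel$ids, paste0("PC", seq_len(n_pcs)))
  pcs
}

#' Principal components from a SNP subset
#'
#' Builds a GRM restricted to the given SNPs (e.g. a user-supplied list of
#' trait-associated markers) and returns its leading principal components.
#' The list is treated as a set: its order does not matter.
#'
#' @param geno a `holo_geno`.
#' @param snp_list character vector of SNP ids, a subset of
#'   `geno$snps$snp_id`.
#' @param n_pcs number of components (default 2).
#' @param dialect GRM dialect, see [build_grm()].
#' @return n x n_pcs PC matrix as in [kernel_pca()].
#' @export
snp_subset_pcs <- function(geno, snp_list, n_pcs = 2,
                           dialect = "vanraden") {
  snp_list <- unique(as.character(snp_list))
  if (!length(snp_list))
    stop_hologreml("empty SNP subset", "hologreml_validation_error")
  missing_snps <- setdiff(snp_list, geno$snps$snp_id)
  if (length(missing_snps))
    stop_hologreml(paste0("SNPs not in genotype matrix: ",
                          paste(utils::head(missing_snps, 5), collapse = ", ")),
                   "hologreml_validation_error")
  keep <- geno$snps$snp_id %in% snp_list
  sub <- geno_matrix(geno$calls[, keep, drop = FALSE],
                     geno$individual_ids,
                     geno$snps[keep, , drop = FALSE])
  kernel_pca(build_grm(sub, dialect = dialect), n_pcs)
}
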