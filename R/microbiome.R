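#' Aggregate OTU proportions to genus level
#'
#' A genus's relative abundance in an individual is the sum of the
#' proportions of its member OTUs. OTUs without a genus annotation are
#' pooled under `"unclassified"`, which is carried in the profile but
#' excluded by the genus scans (see [filter_genera()]).
#'
#' @param otu a `holo_otu` with taxonomy.
#' @return An object of class `holo_genus`: list with `abundance`
#'   (genera x individuals), `genera`, `individual_ids`, `mean_abundance`.
#' @export
aggregate_to_genus <- function(otu) {
  genus <- otu$taxonomy$genus
  if (all(genus == "unclassified"))
    stop_hologreml("no OTU has a genus annotation",
                   "hologreml_validation_error")
  groups <- factor(genus, levels = unique(genus))
  agg <- rowsum(otu$abundance, groups, reorder = FALSE)
  structure(list(abundance = agg,
                 genera = rownames(agg),
                 individual_ids = otu$individual_ids,
                 mean_abundance = rowMeans(agg)),
            class = "holo_genus")
}

#' @export
print.holo_genus <- function(x, ...) {
  cat(sprintf("<holo_genus> %d genera x %d individuals\n",
              length(x$genera), length(x$individual_ids)))
  invisible(x)
}

#' Filter genera by mean relative abundance
#'
#' Keeps genera whose across-individual mean relative abundance is
#' strictly greater than `min_mean` (default 1e-4, i.e. 0.01%), the
#' screening threshold used before the association and divergent-group
#' scans. `"unclassified"` is always dropped. Order is preserved.
#'
#' @param gp a `holo_genus`.
#' @param min_mean threshold on the mean proportion (strict inequality).
#' @return the filtered `holo_genus` (possibly empty, with a warning).
#' @export
filter_genera <- function(gp, min_mean = 1e-4) {
  keep <- gp$mean_abundance > min_mean & gp$genera != "unclassified"
  if (!any(keep))
    warning("no genus exceeds the mean-abundance threshold")
  structure(list(abundance = gp$abundance[keep, , drop = FALSE],
                 genera = gp$genera[keep],
                 individual_ids = gp$individual_ids,
                 mean_abundance = gp$mean_abundance[keep]),
            class = "holo_genus")
}

#' Per-individual alpha diversity
#'
#' Observed richness, Shannon (`-sum p log p`), Simpson concentration
#' (`sum p^2`; small = diverse) from proportions; Chao1 and ACE from raw
#' counts via `vegan::estimateR` (they need singleton/doubleton counts, so
#' they are `NA` when the table holds no counts).
#'
#' @param otu a `holo_otu`.
#' @return data.frame with one row per individual: `IID`, `sobs`, `chao1`,
#'   `ace`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(otu) {
  P <- otu$abundance
  shannon <- apply(P, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  simpson <- colSums(P^2)
  sobs <- colSums(P > 0)
  chao1 <- ace <- rep(NA_real_, ncol(P))
  if (!is.null(otu$counts)) {
    if (any(otu$counts < 0))
      stop_hologreml("negative counts", "hologreml_validation_error")
    est <- vegan::estimateR(t(otu$counts))
    chao1 <- unname(est["S.chao1", ])
    ace <- unname(est["S.ACE", ])
    sobs <- unname(est["S.obs", ])
  }
  data.frame(IID = otu$individual_ids, sobs = sobs, chao1 = chao1,
             ace = ace, shannon = unname(shannon),
             simpson = unname(simpson),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the microbial relationship matrix
#'
#' Microbial similarity between individuals i and j is the average, over
#' OTUs, of the product of their standardized abundances:
#' `m_ij = (1/N) sum_o (X_io - Xbar_o)(X_jo - Xbar_o) / s2_o`,
#' with `Xbar_o` the population mean relative abundance of OTU o and
#' `s2_o` its sample variance (n-1 denominator). OTUs with zero variance
#' across individuals carry no similarity information and are dropped
#' before computing; N counts the retained OTUs. With the n-1 convention
#' the trace is exactly n-1 and every row sums to zero.
#'
#' @param otu a `holo_otu` with at least 2 individuals.
#' @return a `holo_kernel` of kind `"MRM"`, with attribute `n_otus_used`.
#' @export
build_mrm <- function(otu) {
  X <- t(otu$abundance)              # individuals x OTUs
  n <- nrow(X)
  if (n < 2)
    stop_hologreml("MRM needs at least 2 individuals",
                   "hologreml_validation_error")
  v <- apply(X, 2, stats::var)
  keep <- v > 0
  if (!any(keep))
    stop_hologreml("all OTUs have zero variance across individuals",
                   "hologreml_validation_error")
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("build_mrm: dropped %d zero-variance OTU(s)", n_dropped))
  Z <- scale(X[, keep, drop = FALSE], center = TRUE, scale = sqrt(v[keep]))
  M <- tcrossprod(Z) / sum(keep)
  k <- kernel_matrix(M, otu$individual_ids, "MRM")
  attr(k, "n_otus_used") <- sum(keep)
  k
}
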