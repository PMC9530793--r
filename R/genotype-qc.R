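#' Per-SNP allele statistics
#'
#' Computes, over non-missing calls at each SNP: the coded-allele frequency
#' `p = (2 n_AA + n_Aa) / (2 n_nonmiss)` (A = the counted A1 allele, so a
#' call of 2 is AA), the call rate, the three genotype counts, and the
#' exact Hardy-Weinberg equilibrium p-value. SNPs with no non-missing call
#' are flagged undefined (`p = NA`) and excluded by [qc_filter()].
#'
#' @param geno a `holo_geno`.
#' @return data.frame with one row per SNP: `snp_id`, `n_AA`, `n_Aa`,
#'   `n_aa`, `call_rate`, `p`, `maf`, `hwe_p`.
#' @export
allele_stats <- function(geno) {
  calls <- geno$calls
  n_ind <- nrow(calls)
  n_AA <- colSums(calls == 2L, na.rm = TRUE)
  n_Aa <- colSums(calls == 1L, na.rm = TRUE)
  n_aa <- colSums(calls == 0L, na.rm = TRUE)
  n_obs <- n_AA + n_Aa + n_aa
  p <- ifelse(n_obs > 0, (2 * n_AA + n_Aa) / (2 * n_obs), NA_real_)
  hwe_p <- rep(NA_real_, ncol(calls))
  ok <- n_obs > 0
  hwe_p[ok] <- mapply(hwe_exact_test, n_AA[ok], n_Aa[ok], n_aa[ok])
  data.frame(snp_id = geno$snps$snp_id,
             n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
             call_rate = n_obs / n_ind,
             p = p,
             maf = pmin(p, 1 - p),
             hwe_p = hwe_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts
#' (Wigginton-style enumeration): the p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count. Mid-p is not applied.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts.
#' @return p-value in (0, 1]; `NA` when all counts are zero.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(NA_real_)
  nA <- 2 * n_AA + n_Aa          # rarer-vs-common symmetric: use as-is
  na_ <- 2 * n_aa + n_Aa
  n_rare <- min(nA, na_)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log conditional probability of each het count given allele counts:
  # P(nAb) = n! nA! na! 2^nAb / [ (2n)! nAA! nAb! naa! ]
  n_AA_h <- (n_rare - hets) / 2
  n_aa_h <- n - hets - n_AA_h
  logp <- lgamma(n + 1) - lgamma(n_AA_h + 1) - lgamma(hets + 1) -
    lgamma(n_aa_h + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(na_ + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' SNP quality-control filter
#'
#' Retains SNPs passing all three criteria: call rate strictly above
#' `call_rate_min`, minor allele frequency strictly above `maf_min`, and
#' exact HWE p-value at or above `hwe_p_min` (a SNP with p exactly at the
#' threshold is kept). SNPs with zero non-missing calls are always removed.
#' The criteria are independent per SNP, so their application order cannot
#' change the retained set.
#'
#' @param geno a `holo_geno`.
#' @param call_rate_min minimum call rate (default 0.8).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min HWE p-value threshold (default 1e-6).
#' @return the filtered `holo_geno`, with a `qc_report` attribute: a list
#'   of per-criterion removal counts and the retained SNP count.
#' @export
qc_filter <- function(geno, call_rate_min = 0.8, maf_min = 0.01,
                      hwe_p_min = 1e-6) {
  stats <- allele_stats(geno)
  undefined <- is.na(stats$p)
  fail_call <- !undefined & stats$call_rate <= call_rate_min
  fail_maf <- !undefined & stats$maf <= maf_min
  fail_hwe <- !undefined & stats$hwe_p < hwe_p_min
  keep <- !(undefined | fail_call | fail_maf | fail_hwe)
  if (!any(keep))
    stop_hologreml("no SNPs pass QC", "hologreml_validation_error")
  report <- list(n_input = nrow(stats),
                 n_removed_undefined = sum(undefined),
                 n_removed_call_rate = sum(fail_call),
                 n_removed_maf = sum(fail_maf),
                 n_removed_hwe = sum(fail_hwe),
                 n_removed_total = sum(!keep),
                 n_retained = sum(keep),
                 thresholds = c(call_rate = call_rate_min, maf = maf_min,
                                hwe_p = hwe_p_min))
  out <- geno_matrix(geno$calls[, keep, drop = FALSE],
                     geno$individual_ids,
                     geno$snps[keep, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}
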