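# Shared fixture builders. Everything is generated in code; the only
# RNG used is seeded locally inside each helper call.

snp_meta <- function(ids) {
  data.frame(snp_id = ids, chrom = "1", pos = seq_along(ids) * 100L,
             allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
}

make_geno <- function(calls, ids = NULL, snp_ids = NULL) {
  calls <- as.matrix(calls)
  ids <- ids %||% sprintf("i%02d", seq_len(nrow(calls)))
  snp_ids <- snp_ids %||% sprintf("s%02d", seq_len(ncol(calls)))
  geno_matrix(calls, ids, snp_meta(snp_ids))
}

flat_tax <- function(otu_ids, genus = NULL) {
  data.frame(otu_id = otu_ids,
             phylum = "P", class = "C", order = "O", family = "F",
             genus = genus %||% paste0("g_", otu_ids),
             stringsAsFactors = FALSE)
}

make_otu <- function(abundance, ids = NULL, otu_ids = NULL, genus = NULL,
                     counts = NULL) {
  abundance <- as.matrix(abundance)
  otu_ids <- otu_ids %||% sprintf("otu%02d", seq_len(nrow(abundance)))
  ids <- ids %||% sprintf("i%02d", seq_len(ncol(abundance)))
  otu_abundance(abundance, otu_ids, ids, flat_tax(otu_ids, genus),
                counts = counts)
}

# holo_otu with the abundance matrix taken verbatim (no per-individual
# renormalization) — for exercising the MRM formula on raw profiles
raw_otu <- function(abundance) {
  abundance <- as.matrix(abundance)
  otu_ids <- sprintf("otu%02d", seq_len(nrow(abundance)))
  ids <- sprintf("i%02d", seq_len(ncol(abundance)))
  dimnames(abundance) <- list(otu_ids, ids)
  structure(list(abundance = abundance, otu_ids = otu_ids,
                 individual_ids = ids, taxonomy = flat_tax(otu_ids),
                 counts = NULL), class = "holo_otu")
}

# a well-conditioned PSD kernel with strong eigen-structure (r informative
# directions), mean diagonal ~1 — identifiable in single-kernel REML
make_structured_kernel <- function(n, r = 50, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * r), n)
  K <- tcrossprod(scale(Z)) / r
  K / mean(diag(K))
}

# draw y = kernel effect + noise with a given variance fraction
draw_kernel_trait <- function(K, fraction, seed) {
  set.seed(seed)
  n <- nrow(K)
  g <- sqrt(fraction) * drop(crossprod(chol(K + 1e-8 * diag(n)), rnorm(n)))
  g + rnorm(n, 0, sqrt(1 - fraction))
}

# brute-force two-sided Wilcoxon rank-sum p by full enumeration of all
# assignments of the pooled values to the two groups (tie-free inputs)
wilcoxon_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  r_all <- apply(sets, 2, function(idx) sum(rank(pooled)[idx]))
  p_le <- mean(r_all <= r_obs)
  p_ge <- mean(r_all >= r_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force exact HWE p: enumerate every heterozygote count compatible
# with the observed allele counts, probabilities from the literal
# factorial formula, normalized by their sum
hwe_enum_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nb <- 2 * n_aa + n_Aa
  hets <- seq(min(nA, nb) %% 2, min(nA, nb), by = 2)
  pr <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nb - h) / 2
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs + 1e-12])
}
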