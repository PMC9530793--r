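#' Configuration for the synthetic hologenome generator
#'
#' Defaults describe a desk-scale version of a livestock hologenome
#' study: a few hundred individuals, thousands of independent biallelic
#' SNPs with uniform-drawn allele frequencies, a compositional OTU table
#' with a few dominant taxa and a heavy right tail, and a quantitative
#' trait assembled from kernel-distributed genetic, microbial and
#' interaction effects plus sex, body-weight and residual terms.
#'
#' @param n_individuals sample size (default 300).
#' @param n_snps number of independent SNPs (default 3000).
#' @param maf_range allele-frequency range for the uniform draw,
#'   within (0, 0.5] (default c(0.05, 0.5)).
#' @param n_otus number of OTUs (default 300).
#' @param n_genera number of synthetic genera the OTUs are assigned to
#'   (default 30).
#' @param otu_location_sd SD of per-OTU log-abundance locations; larger
#'   values concentrate the community in fewer taxa (default 2).
#' @param otu_indiv_sd SD of the per-individual log-abundance noise
#'   around each OTU's location (default 1).
#' @param fractions named vector c(g=, m=, a=, e=) of true variance
#'   fractions, non-negative, summing to 1 (default 0.5/0.2/0.1/0.2).
#' @param mu trait intercept (default 6.5, a leaf-fat-percent scale).
#' @param sex_effect additive shift for males (default 0.5).
#' @param bw_slope trait change per kg of body weight (default 0.02).
#' @param bw_mean,bw_sd body-weight distribution in kg (default 100, 10).
#' @param seed RNG seed.
#' @return list of class `holo_simconfig`.
#' @export
sim_config <- function(n_individuals = 300, n_snps = 3000,
                       maf_range = c(0.05, 0.5), n_otus = 300,
                       n_genera = 30, otu_location_sd = 2,
                       otu_indiv_sd = 1,
                       fractions = c(g = 0.5, m = 0.2, a = 0.1, e = 0.2),
                       mu = 6.5, sex_effect = 0.5, bw_slope = 0.02,
                       bw_mean = 100, bw_sd = 10, seed = 1) {
  fractions <- fractions[c("g", "m", "a", "e")]
  if (any(is.na(fractions)) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_hologreml("fractions must be named g/m/a/e, non-negative, sum 1",
                   "hologreml_validation_error")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_hologreml("maf_range must lie within (0, 0.5]",
                   "hologreml_validation_error")
  structure(as.list(environment()), class = "holo_simconfig")
}

#' Simulate a hologenome dataset with known variance fractions
#'
#' Draws genotypes `Binomial(2, p_j)` per SNP, OTU profiles as
#' exponentiated Gaussian log-abundances renormalized per individual to
#' proportions (heavy-tailed, few dominant taxa), builds the standardized
#' GRM, MRM and Hadamard interaction kernels from the simulated data, and
#' assembles the trait as
#' `y = mu + sex_effect * male + bw_slope * (BW - mean) + g + m + a + e`
#' with `g ~ N(0, f_g G)`, `m ~ N(0, f_m M)`, `a ~ N(0, f_a A)`,
#' `e ~ N(0, f_e I)` — total random variance 1, split per
#' `config$fractions`. Everything is reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `holo_sim`: `geno` (`holo_geno`), `otu`
#'   (`holo_otu`), `pheno` (data.frame IID/trait/sex/BW), `kernels`
#'   (list g/m/a of standardized `holo_kernel`s), `true` (fractions and
#'   the realized g/m/a/e draws), `config`.
#' @export
simulate_hologenome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("ind%04d", seq_len(n))

  # genotypes: independent biallelic SNPs, allele frequencies U(maf range)
  p <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  calls <- matrix(stats::rbinom(n * config$n_snps, 2L,
                                rep(p, each = n)),
                  nrow = n)
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(config$n_snps)),
                     chrom = "1",
                     pos = seq_len(config$n_snps) * 100L,
                     allele1 = "A", allele2 = "B",
                     stringsAsFactors = FALSE)
  geno <- geno_matrix(calls, ids, snps)

  # OTU proportions: per-OTU lognormal locations (few dominant taxa),
  # per-individual lognormal noise, renormalized to proportions
  loc <- stats::rnorm(config$n_otus, 0, config$otu_location_sd)
  logab <- matrix(stats::rnorm(config$n_otus * n, rep(loc, n),
                               config$otu_indiv_sd),
                  nrow = config$n_otus)
  ab <- exp(logab)
  otu_ids <- sprintf("otu%04d", seq_len(config$n_otus))
  genus_of <- sprintf("Genus%03d",
                      rep_len(seq_len(config$n_genera), config$n_otus))
  tax <- data.frame(otu_id = otu_ids,
                    phylum = sprintf("Phylum%02d",
                                     rep_len(1:4, config$n_otus)),
                    class = "SyntheticClass", order = "SyntheticOrder",
                    family = "SyntheticFamily", genus = genus_of,
                    stringsAsFactors = FALSE)
  otu <- otu_abundance(ab, otu_ids, ids, tax)

  # kernels from the realized data, standardized to mean diagonal 1; the
  # genomic kernel uses the polymorphic SNPs (a finite sample can fix a
  # low-MAF SNP; such SNPs stay in the genotype output for QC to handle)
  pbar <- colMeans(calls) / 2
  poly <- pbar > 0 & pbar < 1
  geno_poly <- geno_matrix(calls[, poly, drop = FALSE], ids,
                           snps[poly, , drop = FALSE])
  Gk <- standardize_kernel(build_grm(geno_poly))
  Mk <- standardize_kernel(build_mrm(otu))
  Ak <- standardize_kernel(interaction_kernel(Gk, Mk))

  draw_effect <- function(K, f) {
    if (f == 0) return(rep(0, n))
    ch <- tryCatch(chol(K + 1e-8 * diag(n)), error = function(e) NULL)
    if (is.null(ch))
      stop_hologreml("realized kernel is not positive semi-definite",
                     "hologreml_numeric_error")
    sqrt(f) * drop(crossprod(ch, stats::rnorm(n)))
  }
  f <- config$fractions
  g_eff <- draw_effect(Gk$K, f[["g"]])
  m_eff <- draw_effect(Mk$K, f[["m"]])
  a_eff <- draw_effect(Ak$K, f[["a"]])
  e_eff <- stats::rnorm(n, 0, sqrt(f[["e"]]))

  sex <- factor(rep_len(c("M", "F"), n), levels = c("F", "M"))
  bw <- stats::rnorm(n, config$bw_mean, config$bw_sd)
  y <- config$mu + config$sex_effect * (sex == "M") +
    config$bw_slope * (bw - mean(bw)) + g_eff + m_eff + a_eff + e_eff

  pheno <- data.frame(IID = ids, trait = y, sex = sex, BW = bw,
                      stringsAsFactors = FALSE)
  structure(list(geno = geno, otu = otu, pheno = pheno,
                 kernels = list(g = Gk, m = Mk, a = Ak),
                 true = list(fractions = f,
                             effects = list(g = g_eff, m = m_eff,
                                            a = a_eff, e = e_eff)),
                 config = config),
            class = "holo_sim")
}

#' @export
print.holo_sim <- function(x, ...) {
  cat(sprintf(
    "<holo_sim> n = %d, %d SNPs, %d OTUs; true fractions g/m/a/e = %s\n",
    x$config$n_individuals, x$config$n_snps, x$config$n_otus,
    paste(x$true$fractions, collapse = "/")))
  invisible(x)
}

#' Write a simulated dataset as analysis-ready files
#'
#' Emits `geno.bed/.bim/.fam` (PLINK 1 binary), `otu.tsv` (proportions
#' with taxonomy) and `pheno.tsv` — the exact formats the readers in this
#' package consume, so a written fixture round-trips with zero loss of
#' genotype calls and abundance values.
#'
#' @param sim a `holo_sim`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_plink(sim$geno, file.path(dir, "geno"))
  write_otu_table(sim$otu, file.path(dir, "otu.tsv"))
  utils::write.table(sim$pheno, file.path(dir, "pheno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
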