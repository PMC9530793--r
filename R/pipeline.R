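#' Run the full variance-decomposition and candidate-microbe analysis
#'
#' End-to-end driver: harmonizes ids, applies SNP QC, builds the
#' standardized GRM, MRM and interaction kernels, then per trait
#'
#' 1. fits the three-kernel model (g + m + a + e) and reports variance
#'    fractions with likelihood-ratio p-values,
#' 2. estimates heritability (sex + BW covariates) and microbiability
#'    under the BIC-selected covariate set,
#' 3. runs the divergent-group Wilcoxon scan and the per-genus
#'    association scan on genera above the mean-abundance threshold,
#' 4. intersects the two screens into a candidate-genus list.
#'
#' All thresholds used (QC, genus filter, group fraction, alpha) are
#' recorded in the returned `params` so every output table is auditable.
#' When `out_dir` is given, each table is also written as TSV plus one
#' JSON summary; re-running with identical inputs reproduces the files.
#'
#' @param geno a `holo_geno`.
#' @param otu a `holo_otu`.
#' @param pheno phenotype data.frame with `IID`, trait columns, `sex`,
#'   `BW`.
#' @param traits character vector of trait column names.
#' @param snp_list optional SNP ids for the trait-associated subset PCs
#'   (enables all six covariate sets; without it only sets 1 and 4 are
#'   screened).
#' @param qc list of QC thresholds (`call_rate`, `maf`, `hwe_p`).
#' @param genus_min_mean genus mean-abundance threshold (default 1e-4).
#' @param fraction divergent-group fraction (default 0.2).
#' @param alpha significance level (default 0.05).
#' @param grm_dialect GRM dialect for the interaction model
#'   (default "vanraden").
#' @param mwas_kinship use the GRM as the association-scan random effect
#'   (default TRUE).
#' @param out_dir optional output directory for TSV/JSON reports.
#' @return list of class `holo_run`: `params`, `qc_report`, `kernels`,
#'   and per-trait `interaction_fit` (fractions table + p-values),
#'   `heritability`, `microbiability` (with the BIC table),
#'   `divergent`, `mwas`, `candidates`.
#' @export
run_all <- function(geno, otu, pheno, traits, snp_list = NULL,
                    qc = list(call_rate = 0.8, maf = 0.01, hwe_p = 1e-6),
                    genus_min_mean = 1e-4, fraction = 0.2, alpha = 0.05,
                    grm_dialect = "vanraden", mwas_kinship = TRUE,
                    out_dir = NULL) {
  missing_traits <- setdiff(traits, names(pheno))
  if (length(missing_traits))
    stop_hologreml(paste0("traits not in phenotype table: ",
                          paste(missing_traits, collapse = ", ")),
                   "hologreml_validation_error")
  h <- harmonize_ids(geno, otu, pheno)
  geno <- h$geno; otu <- h$otu; pheno <- h$pheno

  geno_qc <- qc_filter(geno, qc$call_rate, qc$maf, qc$hwe_p)
  qc_report <- attr(geno_qc, "qc_report")

  # kernel cache: recomputing the GRM dominates a re-run, so kernels are
  # stored under out_dir/cache and reused bit-identically when present
  cache_path <- if (!is.null(out_dir))
    file.path(out_dir, "cache", "kernels.rds") else NULL
  if (!is.null(cache_path) && file.exists(cache_path)) {
    kl <- readRDS(cache_path)
    Gk <- kl$g; Mk <- kl$m; Ak <- kl$a; Gk_gcta <- kl$g_gcta
  } else {
    Gk <- standardize_kernel(build_grm(geno_qc, dialect = grm_dialect))
    Mk <- standardize_kernel(build_mrm(otu))
    Ak <- standardize_kernel(interaction_kernel(Gk, Mk))
    Gk_gcta <- standardize_kernel(build_grm(geno_qc, dialect = "gcta"))
    if (!is.null(cache_path)) {
      dir.create(dirname(cache_path), recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(g = Gk, m = Mk, a = Ak, g_gcta = Gk_gcta), cache_path)
    }
  }

  gp <- filter_genera(aggregate_to_genus(otu), genus_min_mean)
  grm_pcs <- kernel_pca(Gk, 5)
  subset_pcs <- if (!is.null(snp_list))
    snp_subset_pcs(geno_qc, snp_list, 2, dialect = grm_dialect) else NULL

  per_trait <- lapply(traits, function(tr) {
    y <- pheno[[tr]]
    base_cov <- data.frame(sex = pheno$sex, BW = pheno$BW)

    # (1) multi-kernel interaction model: intercept-only fixed effects
    fit3 <- reml_fit(y[is.finite(y)], NULL,
                     lapply(list(g = Gk, m = Mk, a = Ak),
                            function(k) k$K[is.finite(y), is.finite(y)]),
                     trait = tr)
    pvals3 <- component_pvalues(fit3)
    frac_tab <- variance_fractions(fit3)
    frac_tab$p_lrt <- c(pvals3[frac_tab$component[-nrow(frac_tab)]], NA)

    # (2) heritability (GCTA-form GRM, sex + BW) and BIC-selected
    # microbiability
    h2 <- heritability(y, base_cov, Gk_gcta, trait = tr)
    sets <- covariate_sets(pheno$BW, pheno$sex, grm_pcs, subset_pcs)
    sel <- select_covariates(y, sets, Mk, trait = tr)

    # (3) screens over genera, (4) intersection
    ok <- is.finite(y)
    gp_t <- gp
    gp_t$abundance <- gp$abundance[, ok, drop = FALSE]
    gp_t$individual_ids <- gp$individual_ids[ok]
    div <- divergent_scan(y[ok], gp_t, fraction, alpha)
    mw <- mwas_scan(y[ok], gp_t,
                    covariates = base_cov[ok, , drop = FALSE],
                    kinship = if (mwas_kinship)
                      kernel_matrix(Gk$K[ok, ok], gp_t$individual_ids,
                                    "GRM") else NULL,
                    alpha = alpha)
    list(trait = tr,
         interaction_fit = fit3,
         interaction_table = frac_tab,
         heritability = h2,
         microbiability = sel$fit,
         covariate_selection = sel,
         divergent = div,
         mwas = mw,
         candidates = candidate_intersection(div, mw, alpha))
  })
  names(per_trait) <- traits

  out <- structure(list(
    params = list(qc = qc, genus_min_mean = genus_min_mean,
                  fraction = fraction, alpha = alpha,
                  grm_dialect = grm_dialect,
                  n_individuals = length(h$ids),
                  n_snps_qc = ncol(geno_qc$calls),
                  n_genera = length(gp$genera)),
    qc_report = qc_report,
    kernels = list(g = Gk, m = Mk, a = Ak),
    traits = per_trait), class = "holo_run")
  if (!is.null(out_dir)) write_run_reports(out, out_dir)
  out
}

#' @export
print.holo_run <- function(x, ...) {
  cat(sprintf("<holo_run> %d individuals, %d QC'd SNPs, %d genera; traits: %s\n",
              x$params$n_individuals, x$params$n_snps_qc,
              x$params$n_genera,
              paste(names(x$traits), collapse = ", ")))
  invisible(x)
}

# TSV + JSON reports mirroring the result-table layouts; fractions are
# rounded to 2 decimals in the TSVs, full precision goes to the JSON.
write_run_reports <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  summary_list <- list(params = run$params, qc = run$qc_report)
  for (tr in names(run$traits)) {
    res <- run$traits[[tr]]
    itab <- res$interaction_table
    itab$variance <- round(itab$variance, 2)
    wt(itab, sprintf("%s_interaction.tsv", tr))
    h2m2 <- data.frame(
      trait = tr,
      h2 = round(res$heritability$ratio, 2),
      h2_se = round(res$heritability$se_ratio, 2),
      m2 = round(res$microbiability$ratio, 2),
      m2_se = round(res$microbiability$se_ratio, 2),
      best_covariates = res$covariate_selection$best)
    wt(h2m2, sprintf("%s_h2_m2.tsv", tr))
    wt(res$covariate_selection$table, sprintf("%s_bic.tsv", tr))
    wt(res$divergent, sprintf("%s_divergent.tsv", tr))
    wt(res$mwas, sprintf("%s_mwas.tsv", tr))
    summary_list$traits[[tr]] <- list(
      fractions = as.list(res$interaction_fit$fractions),
      h2 = res$heritability$ratio,
      m2 = res$microbiability$ratio,
      best_covariates = res$covariate_selection$best,
      candidates = res$candidates)
  }
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(summary_list,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
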