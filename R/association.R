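#' Two-sided Wilcoxon rank-sum p-value
#'
#' `mode = "exact"` uses the exact permutation distribution of the
#' rank-sum (valid without ties); `"normal"` uses the tie-corrected normal
#' approximation with continuity correction; `"auto"` picks exact when the
#' combined sample is small (<= 20) and tie-free. If ties make the exact
#' distribution unavailable the tie-corrected normal approximation is used
#' with a warning. Two samples with all values identical carry no ranking
#' information and give p = 1.
#'
#' @param x,y numeric samples, both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop_hologreml("both samples must be non-empty",
                   "hologreml_validation_error")
  vals <- c(x, y)
  if (length(unique(vals)) == 1L) return(1)
  has_ties <- anyDuplicated(vals) > 0
  exact <- switch(mode,
                  exact = TRUE,
                  normal = FALSE,
                  auto = length(vals) <= 20 && !has_ties)
  if (exact && has_ties) {
    warning("ties present; falling back to the tie-corrected normal approximation")
    exact <- FALSE
  }
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
  min(p, 1)
}

#' Extreme divergent groups
#'
#' Indices of the highest and lowest `fraction` of a value vector, with
#' group size `round(fraction * n)` (half rounds up: 239 at 20% gives 48).
#' Ties at the cut are resolved by stable original order; the two groups
#' are always disjoint.
#'
#' @param values numeric vector.
#' @param fraction group fraction in (0, 0.5].
#' @return list with integer index vectors `high` and `low` and the
#'   common `size`.
#' @export
divergent_groups <- function(values, fraction = 0.2) {
  n <- length(values)
  if (fraction <= 0 || fraction > 0.5)
    stop_hologreml("fraction must be in (0, 0.5]",
                   "hologreml_validation_error")
  size <- floor(fraction * n + 0.5)
  if (2 * size > n)
    stop_hologreml("groups would overlap: 2 * size > n",
                   "hologreml_validation_error")
  if (size < 1)
    stop_hologreml("group size is zero at this fraction",
                   "hologreml_validation_error")
  ord_desc <- order(values, seq_len(n), decreasing = c(TRUE, FALSE),
                    method = "radix")
  high <- ord_desc[seq_len(size)]
  ord_asc <- order(values, seq_len(n), method = "radix")
  low <- setdiff(ord_asc, high)[seq_len(size)]
  list(high = sort(high), low = sort(low), size = size)
}

#' Divergent-group Wilcoxon scan over genera
#'
#' For each genus, two complementary rank-sum tests at the `fraction`
#' extremes: (i) genus abundance compared between the highest- and
#' lowest-trait groups (`p_trait_m`), and (ii) the trait compared between
#' the highest- and lowest-abundance groups (`p_m_trait`). A genus is
#' flagged (`significant_both`) when both p-values fall below `alpha`.
#' Group means and SDs are reported for both directions. A genus constant
#' across all individuals gets p = 1 in both directions and a flag.
#'
#' @param trait numeric trait vector, one per individual, same order as
#'   the profile columns.
#' @param gp a `holo_genus`, already filtered ([filter_genera()]).
#' @param fraction extreme-group fraction (default 0.2).
#' @param alpha significance level (default 0.05).
#' @param mode Wilcoxon mode, see [wilcoxon_rank_sum()].
#' @return data.frame, one row per genus, Table-style layout:
#'   genus, abundance mean/SD in high/low-trait groups, `p_trait_m`,
#'   trait mean/SD in high/low-abundance groups, `p_m_trait`,
#'   `significant_both`, `constant`.
#' @export
divergent_scan <- function(trait, gp, fraction = 0.2, alpha = 0.05,
                           mode = "auto") {
  stopifnot(length(trait) == length(gp$individual_ids))
  trait_grp <- divergent_groups(trait, fraction)
  rows <- lapply(seq_along(gp$genera), function(i) {
    ab <- gp$abundance[i, ]
    constant <- length(unique(ab)) == 1L
    ab_high <- ab[trait_grp$high]
    ab_low <- ab[trait_grp$low]
    if (constant) {
      p_tm <- p_mt <- 1
      tr_stats <- rep(NA_real_, 4)
    } else {
      p_tm <- wilcoxon_rank_sum(ab_high, ab_low, mode)
      ab_grp <- divergent_groups(ab, fraction)
      tr_high <- trait[ab_grp$high]
      tr_low <- trait[ab_grp$low]
      p_mt <- wilcoxon_rank_sum(tr_high, tr_low, mode)
      tr_stats <- c(mean(tr_high), stats::sd(tr_high),
                    mean(tr_low), stats::sd(tr_low))
    }
    data.frame(genus = gp$genera[i],
               micro_mean_high_trait = mean(ab_high),
               micro_sd_high_trait = stats::sd(ab_high),
               micro_mean_low_trait = mean(ab_low),
               micro_sd_low_trait = stats::sd(ab_low),
               p_trait_m = p_tm,
               trait_mean_high_micro = tr_stats[1],
               trait_sd_high_micro = tr_stats[2],
               trait_mean_low_micro = tr_stats[3],
               trait_sd_low_micro = tr_stats[4],
               p_m_trait = p_mt,
               significant_both = !constant & p_tm < alpha & p_mt < alpha,
               constant = constant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Microbiome-wide association scan
#'
#' Per genus, regresses the trait on that genus's relative abundance with
#' the given covariates: `y = X beta + u + e`. With `kinship = NULL` this
#' is ordinary least squares; with a kernel, `u ~ N(0, K sigma2_u)` and
#' the variance components are estimated once by REML under the
#' genus-free null model, after which each genus is tested by generalized
#' least squares with V held fixed (the standard two-stage mixed-model
#' association strategy). Either way the genus coefficient is tested by a
#' 1-numerator-df F-test; positive beta means higher abundance goes with a
#' higher trait value. A Benjamini-Hochberg column is appended for
#' information; the significance call uses the raw p-values.
#'
#' @param trait numeric trait vector, same order as profile columns.
#' @param gp a `holo_genus`, already filtered ([filter_genera()]).
#' @param covariates data.frame (e.g. sex, BW) or NULL.
#' @param kinship a `holo_kernel` (typically the GRM) or NULL for OLS.
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame: genus, beta, F, p, p_bh, n_used, significant.
#' @export
mwas_scan <- function(trait, gp, covariates = NULL, kinship = NULL,
                      alpha = 0.05) {
  stopifnot(length(trait) == length(gp$individual_ids))
  keep <- is.finite(trait)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(as.data.frame(covariates))
  if (sum(!keep) > 0)
    message(sprintf("dropping %d individual(s) with missing trait/covariates",
                    sum(!keep)))
  y <- trait[keep]
  n <- length(y)
  X0 <- build_design(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[keep, , drop = FALSE], n)
  G <- gp$abundance[, keep, drop = FALSE]

  if (is.null(kinship)) {
    Vinv_half <- NULL
  } else {
    K <- as_kernel_mat(kinship)[keep, keep, drop = FALSE]
    null_fit <- reml_fit(y, X0, list(u = K))
    V <- null_fit$components["u"] * K +
      null_fit$components["e"] * diag(n)
    Vinv_half <- backsolve(chol(V), diag(n), transpose = TRUE)  # L^-1
  }

  rows <- lapply(seq_along(gp$genera), function(i) {
    g <- G[i, ]
    X <- cbind(X0, genus = g)
    if (qr(X)$rank < ncol(X)) {
      warning(sprintf("genus %s: rank-deficient design, skipped",
                      gp$genera[i]))
      return(NULL)
    }
    if (is.null(Vinv_half)) {
      yw <- y
      Xw <- X
    } else {
      yw <- drop(Vinv_half %*% y)
      Xw <- Vinv_half %*% X
    }
    p_cols <- ncol(X)
    XtX_inv <- chol2inv(chol(crossprod(Xw)))
    coefs <- drop(XtX_inv %*% crossprod(Xw, yw))
    rss <- sum((yw - Xw %*% coefs)^2)
    df_res <- n - p_cols
    beta <- coefs[p_cols]
    se <- sqrt(XtX_inv[p_cols, p_cols] * rss / df_res)
    Fstat <- (beta / se)^2
    pval <- stats::pf(Fstat, 1, df_res, lower.tail = FALSE)
    data.frame(genus = gp$genera[i], beta = unname(beta),
               F = unname(Fstat), p = unname(pval), n_used = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < alpha
  out
}

#' Candidate genera supported by both screens
#'
#' Genera flagged in both directions of the divergent-group scan and with
#' an association-scan p-value below `alpha`.
#'
#' @param divergent output of [divergent_scan()].
#' @param mwas output of [mwas_scan()].
#' @param alpha significance level for the association p-value.
#' @return character vector of genus names (possibly empty).
#' @export
candidate_intersection <- function(divergent, mwas, alpha = 0.05) {
  div_sig <- divergent$genus[divergent$significant_both]
  mwas_sig <- mwas$genus[mwas$p < alpha]
  intersect(div_sig, mwas_sig)
}
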