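# Multi-kernel REML engine.
#
# Model: y ~ N(X beta, sum_k sigma2_k K_k + sigma2_e I). The engine
# maximizes the restricted likelihood by average-information (AI) updates
# with an EM first step and EM fallback whenever an AI step leaves the
# feasible region or fails to improve. Components are constrained to
# >= 1e-8 * var(y). With a single kernel the model is rotated to the
# kernel's eigenbasis, which makes V diagonal and each iteration O(n p^2);
# the multi-kernel path works with dense matrices.

# The fixed effects are absorbed once per fit: with Q an orthonormal
# basis of the complement of col(X), the restricted likelihood of y is
# the ordinary likelihood of Q'y ~ N(0, sum_k sigma2_k Q'K_kQ + sigma2_e I).
# Working in this (n-p)-dimensional space removes the fixed-effect
# projection from every quadratic form (no catastrophic cancellation when
# a kernel's null space lies inside col(X)) and makes P simply V^-1.
absorb_fixed <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  Q <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  list(Qt = t(Q), y = drop(crossprod(Q, y)))
}

# One likelihood evaluation in the absorbed space: Ks are the rotated
# kernels (residual identity last), y the rotated response. Returns logL,
# gradient, AI matrix and the quadratic forms the updates need, or NULL
# when V is not positive definite at this point.
reml_eval_dense <- function(sigma2, Ks, y) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(Ks)) V <- V + sigma2[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  Py <- drop(Vinv %*% y)
  logL <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(y * Py))
  if (!is.finite(logL)) return(NULL)
  K_Py <- lapply(Ks, function(K) drop(K %*% Py))
  trPK <- vapply(Ks, function(K) sum(Vinv * K), numeric(1))
  yPKPy <- vapply(K_Py, function(v) sum(Py * v), numeric(1))
  P_KPy <- lapply(K_Py, function(v) drop(Vinv %*% v))
  m <- length(Ks)
  AI <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m)
    AI[i, j] <- AI[j, i] <- 0.5 * sum(K_Py[[i]] * P_KPy[[j]])
  list(logL = logL, grad = -0.5 * (trPK - yPKPy), AI = AI,
       yPKPy = yPKPy, trPK = trPK)
}

# Spectral single-kernel evaluator: y pre-rotated into the absorbed
# kernel's eigenbasis, d = eigenvalues. sigma2 = c(kernel, residual).
# V is diagonal, so an evaluation is O(n).
reml_eval_spectral <- function(sigma2, d, y) {
  n <- length(y)
  w <- sigma2[1] * d + sigma2[2]
  if (any(w <= 0)) return(NULL)
  Py <- y / w
  logL <- -0.5 * (n * log(2 * pi) + sum(log(w)) + sum(y * Py))
  if (!is.finite(logL)) return(NULL)
  ds <- list(d, rep(1, n))
  K_Py <- lapply(ds, function(dd) dd * Py)
  trPK <- vapply(ds, function(dd) sum(dd / w), numeric(1))
  yPKPy <- vapply(K_Py, function(v) sum(Py * v), numeric(1))
  P_KPy <- lapply(K_Py, function(v) v / w)
  AI <- matrix(0, 2, 2)
  for (i in 1:2) for (j in i:2)
    AI[i, j] <- AI[j, i] <- 0.5 * sum(K_Py[[i]] * P_KPy[[j]])
  list(logL = logL, grad = -0.5 * (trPK - yPKPy), AI = AI,
       yPKPy = yPKPy, trPK = trPK)
}

as_kernel_mat <- function(k) {
  if (inherits(k, "holo_kernel")) k$K else as.matrix(k)
}

#' Fit a multi-kernel variance-component model by REML
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(X beta, sum_k sigma2_k K_k + sigma2_e I)` and reports the
#' variance components, their fractions of the total, standard errors
#' (delta method on the inverse average-information matrix), the restricted
#' log-likelihood and BIC.
#'
#' Algorithms: `"ai"` (default) — average-information updates, first step
#' and any failed step replaced by EM; `"em"` — EM only; `"grid"` — for a
#' single kernel, exhaustive evaluation over a 21 x 21 grid of
#' (sigma2_k, sigma2_e), used as a brute-force cross-check of the
#' optimizer. Convergence: `|delta logL| < tol` (default 1e-6) or
#' `max_iter` (default 200) iterations, in which case the fit is flagged
#' unconverged. Components are constrained to `>= 1e-8 * var(y)`. A fit
#' whose AI matrix is numerically singular at the optimum (e.g. a kernel
#' proportional to the identity, which leaves the decomposition
#' unidentifiable) is flagged `identifiable = FALSE` with `NA` standard
#' errors.
#'
#' @param y numeric response vector, no missing values.
#' @param X fixed-effect design matrix (default: intercept only); must be
#'   full column rank.
#' @param kernels named list of `holo_kernel`s or symmetric matrices, all
#'   in the same id order as `y`; names label the components (the residual
#'   is always labelled `"e"`).
#' @param algorithm `"ai"`, `"em"` or `"grid"`.
#' @param max_iter,tol convergence controls.
#' @param start optional vector of starting variance components (one per
#'   kernel plus residual, in that order); default splits var(y) equally.
#' @param constrain keep every component above `1e-8 * var(y)` (default).
#'   `FALSE` allows negative components as long as the total covariance
#'   stays positive definite — the usual remedy when the truncation bias
#'   of constrained estimates matters more than interpretability, as in
#'   unbiasedness studies.
#' @param trait optional trait name carried into reports.
#' @return An object of class `holo_vcfit`: components, fractions, SEs,
#'   `logLik`, `bic`, `k_params`, convergence information.
#' @export
reml_fit <- function(y, X = NULL, kernels, algorithm = c("ai", "em", "grid"),
                     max_iter = 200, tol = 1e-6, start = NULL,
                     constrain = TRUE, trait = NULL) {
  algorithm <- match.arg(algorithm)
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y)))
    stop_hologreml("y contains non-finite values; drop incomplete cases first",
                   "hologreml_validation_error")
  if (n < 30)
    warning("fewer than 30 individuals; variance-component estimates will be unstable")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X))
    stop_hologreml("fixed-effect design is singular",
                   "hologreml_validation_error")
  if (!length(kernels))
    stop_hologreml("at least one kernel required", "hologreml_validation_error")
  if (is.null(names(kernels)) || any(!nzchar(names(kernels))))
    names(kernels) <- paste0("k", seq_along(kernels))
  Ks <- lapply(kernels, as_kernel_mat)
  for (K in Ks)
    if (nrow(K) != n)
      stop_hologreml("kernel dimension does not match y",
                     "hologreml_validation_error")
  labels <- c(names(kernels), "e")
  m <- length(Ks) + 1L
  vy <- stats::var(y)
  lb <- if (constrain) 1e-8 * vy else -Inf

  ab <- absorb_fixed(y, X)
  yq <- ab$y
  nq <- length(yq)
  Kq <- lapply(Ks, function(K) tcrossprod(ab$Qt %*% K, ab$Qt))
  if (length(Ks) == 1L) {
    eig <- eigen(Kq[[1]], symmetric = TRUE)
    yr <- drop(crossprod(eig$vectors, yq))
    evalf <- function(s2) reml_eval_spectral(s2, eig$values, yr)
  } else {
    KqI <- c(Kq, list(diag(nq)))
    evalf <- function(s2) reml_eval_dense(s2, KqI, yq)
  }

  if (algorithm == "grid") {
    if (length(Ks) != 1L)
      stop_hologreml("grid search supports exactly one kernel",
                     "hologreml_validation_error")
    grid_vals <- seq(0.01, 1.5, length.out = 21) * vy
    best <- NULL
    for (sg in grid_vals) for (se in grid_vals) {
      ev <- evalf(c(sg, se))
      if (!is.null(ev) && (is.null(best) || ev$logL > best$logL))
        best <- list(logL = ev$logL, s2 = c(sg, se))
    }
    sigma2 <- best$s2
    ev <- evalf(sigma2)
    return(finish_vcfit(sigma2, ev, labels, n, ncol(X), vy, TRUE, 0L,
                        "grid", trait, y, X, kernels))
  }

  sigma2 <- if (is.null(start)) rep(vy / m, m) else pmax(start, lb)
  if (length(sigma2) != m)
    stop_hologreml("start must have one value per kernel plus residual",
                   "hologreml_validation_error")
  ev <- evalf(sigma2)
  if (is.null(ev))
    stop_hologreml("likelihood not finite at the starting point",
                   "hologreml_numeric_error")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    prop <- NULL
    ev_new <- NULL
    if (algorithm == "ai" && it > 1L) {
      # active-set AI step: components pinned at the lower bound with a
      # non-positive gradient are held fixed and excluded from the solve,
      # released automatically when their gradient turns positive
      free <- !(sigma2 <= lb * (1 + 1e-6) & ev$grad <= 0)
      if (any(free)) {
        delta <- tryCatch(
          solve(ev$AI[free, free, drop = FALSE], ev$grad[free]),
          error = function(e) NULL)
        if (!is.null(delta)) {
          step <- 1
          while (step >= 1 / 128) {
            cand <- sigma2
            cand[free] <- pmax(sigma2[free] + step * delta, lb)
            ev_c <- evalf(cand)
            if (!is.null(ev_c) && ev_c$logL >= ev$logL - 1e-10) {
              prop <- cand
              ev_new <- ev_c
              break
            }
            step <- step / 2
          }
        }
      }
    }
    if (is.null(prop)) {                        # EM step / fallback
      prop <- pmax(sigma2 + sigma2^2 * (ev$yPKPy - ev$trPK) / n, lb)
      ev_new <- evalf(prop)
      if (is.null(ev_new) && !constrain) {
        # unconstrained fit wandered to a non-PD point; pull back inside
        prop <- pmax(prop, 1e-8 * vy)
        ev_new <- evalf(prop)
      }
      if (is.null(ev_new))
        stop_hologreml(
          sprintf("non-finite likelihood at iteration %d (components: %s)",
                  it, paste(signif(prop, 4), collapse = ", ")),
          "hologreml_numeric_error")
    }
    dlogL <- ev_new$logL - ev$logL
    sigma2 <- prop
    ev <- ev_new
    free_now <- !(sigma2 <= lb * (1 + 1e-6) & ev$grad <= 0)
    grad_ok <- algorithm == "em" || !any(free_now) ||
      max(abs(ev$grad[free_now])) < 1e-3 * n
    if (abs(dlogL) < tol && grad_ok) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("REML did not converge in %d iterations (|dlogL| last = %.2e)",
                    max_iter, abs(dlogL)))
  finish_vcfit(sigma2, ev, labels, n, ncol(X), vy, converged, it,
               algorithm, trait, y, X, kernels)
}

finish_vcfit <- function(sigma2, ev, labels, n, p, vy, converged, iterations,
                         algorithm, trait, y, X, kernels) {
  m <- length(sigma2)
  names(sigma2) <- labels
  total <- sum(sigma2)
  fractions <- sigma2 / total
  rc <- tryCatch(1 / kappa(ev$AI, exact = TRUE), error = function(e) 0)
  identifiable <- is.finite(rc) && rc > 1e-10
  se <- se_frac <- rep(NA_real_, m)
  if (identifiable) {
    AIinv <- solve(ev$AI)
    se <- sqrt(pmax(diag(AIinv), 0))
    J <- (diag(m) * total - matrix(sigma2, m, m, byrow = FALSE)) / total^2
    se_frac <- sqrt(pmax(diag(J %*% AIinv %*% t(J)), 0))
  }
  names(se) <- names(se_frac) <- names(fractions) <- labels
  k_params <- m + p
  structure(list(trait = trait,
                 components = sigma2,
                 fractions = fractions,
                 se_components = se,
                 se_fractions = se_frac,
                 total_variance = total,
                 logLik = ev$logL,
                 bic = bic_value(ev$logL, k_params, n),
                 n = n, p_fixed = p, k_params = k_params,
                 converged = converged, iterations = iterations,
                 grad_norm = sqrt(sum(ev$grad^2)),
                 identifiable = identifiable,
                 algorithm = algorithm,
                 y = y, X = X, kernels = kernels),
            class = "holo_vcfit")
}

#' @export
print.holo_vcfit <- function(x, ...) {
  cat(sprintf("<holo_vcfit%s> n = %d, logL = %.4f, BIC = %.3f%s%s\n",
              if (!is.null(x$trait)) paste0(" ", x$trait) else "",
              x$n, x$logLik, x$bic,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (!x$identifiable) " [NOT IDENTIFIABLE]" else ""))
  print(round(rbind(variance = x$components, fraction = x$fractions,
                    se_fraction = x$se_fractions), 4))
  invisible(x)
}

#' Variance fractions table
#'
#' One row per component (residual included): variance, fraction of total
#' phenotypic variance `sigma2_x / sigma2_p` (the total is the sum of all
#' fitted components, residual included), standard errors when available,
#' plus the fractions rounded to 2 decimals as reported.
#'
#' @param fit a `holo_vcfit`, or a named numeric vector of variance
#'   components (e.g. `c(g = 1.54, m = 0.19, a = 0.26, e = 0)`).
#' @return data.frame with columns `component`, `variance`, `fraction`,
#'   `se_fraction`, `fraction_2dp`.
#' @export
variance_fractions <- function(fit) {
  if (is.numeric(fit)) {
    total <- sum(fit)
    if (total <= 0)
      stop_hologreml("total variance is zero", "hologreml_validation_error")
    return(data.frame(component = names(fit) %||% paste0("k", seq_along(fit)),
                      variance = unname(fit),
                      fraction = unname(fit) / total,
                      se_fraction = NA_real_,
                      fraction_2dp = round(unname(fit) / total, 2),
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  if (fit$total_variance <= 0)
    stop_hologreml("total variance is zero", "hologreml_validation_error")
  data.frame(component = names(fit$components),
             variance = unname(fit$components),
             fraction = unname(fit$fractions),
             se_fraction = unname(fit$se_fractions),
             fraction_2dp = round(unname(fit$fractions), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bayesian information criterion
#'
#' `BIC = k ln(n) - 2 ln(L)`; smaller is better. For a fitted
#' variance-component model `k` counts the estimated variance parameters
#' (residual included) plus the fixed effects.
#'
#' @param logLik log-likelihood value.
#' @param k number of model parameters.
#' @param n sample size.
#' @return the BIC value.
#' @export
bic_value <- function(logLik, k, n) k * log(n) - 2 * logLik

#' @rdname bic_value
#' @param fit a `holo_vcfit`.
#' @export
bic <- function(fit) fit$bic

# Build X from a covariate data.frame (factors expanded), with the ids
# used; returns NULL design (intercept only) when covariates is NULL.
build_design <- function(covariates, n) {
  if (is.null(covariates))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., data = as.data.frame(covariates))
}

# Complete-case restriction shared by the single-kernel front-ends.
complete_case <- function(y, covariates, kernel) {
  keep <- is.finite(y)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(as.data.frame(covariates))
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("dropping %d individual(s) with missing trait/covariates",
                    n_drop))
  K <- as_kernel_mat(kernel)
  list(y = y[keep],
       covariates = if (is.null(covariates)) NULL else
         as.data.frame(covariates)[keep, , drop = FALSE],
       K = K[keep, keep, drop = FALSE],
       n_dropped = n_drop)
}

fit_single_kernel <- function(y, covariates, kernel, label, trait = NULL,
                              ...) {
  cc <- complete_case(y, covariates, kernel)
  X <- build_design(cc$covariates, length(cc$y))
  ks <- list(cc$K)
  names(ks) <- label
  fit <- reml_fit(cc$y, X, ks, trait = trait, ...)
  fit$ratio <- unname(fit$fractions[label])
  fit$se_ratio <- unname(fit$se_fractions[label])
  fit$n_dropped <- cc$n_dropped
  fit
}

#' Heritability from a genomic relationship matrix
#'
#' Single-kernel REML fit `y = X c + g + e` with `g ~ N(0, G sigma2_g)`;
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)`, reported in `$ratio` with its
#' delta-method standard error in `$se_ratio`. Individuals with missing
#' trait or covariates are dropped (complete-case) with a message.
#'
#' @param y trait vector, same order as the kernel ids.
#' @param covariates data.frame of fixed covariates (e.g. sex, BW) or NULL.
#' @param grm a `holo_kernel` (GRM).
#' @param ... passed to [reml_fit()].
#' @return a `holo_vcfit` with `$ratio` = h2.
#' @export
heritability <- function(y, covariates = NULL, grm, ...) {
  fit_single_kernel(y, covariates, grm, "g", ...)
}

#' Microbiability from a microbial relationship matrix
#'
#' Single-kernel REML fit `y = X c + m + e` with `m ~ N(0, M sigma2_m)`;
#' `m2 = sigma2_m / (sigma2_m + sigma2_e)` — the fraction of phenotypic
#' variance carried by microbiome similarity. Covariates are typically one
#' of the six sets built by [covariate_sets()] and selected by
#' [select_covariates()].
#'
#' @inheritParams heritability
#' @param mrm a `holo_kernel` (MRM).
#' @return a `holo_vcfit` with `$ratio` = m2.
#' @export
microbiability <- function(y, covariates = NULL, mrm, ...) {
  fit_single_kernel(y, covariates, mrm, "m", ...)
}

#' Likelihood-ratio p-value for one variance component
#'
#' `Lambda = 2 (logL_full - logL_reduced)` compared to a 50:50 mixture of
#' a point mass at zero and chi-square(1) — the null distribution when the
#' tested component sits on the boundary of its parameter space. A
#' reduced fit beating the full fit by more than 1e-6 triggers a refit
#' warning (the optimizer missed the optimum).
#'
#' @param fit_full,fit_reduced `holo_vcfit`s; the reduced model drops one
#'   kernel of the full model.
#' @return p-value in (0, 1]; `Lambda = 0` gives 0.5.
#' @export
component_pvalue <- function(fit_full, fit_reduced) {
  lambda <- 2 * (fit_full$logLik - fit_reduced$logLik)
  if (lambda < -1e-6)
    warning("reduced model has higher likelihood than the full model; refit")
  lambda <- max(lambda, 0)
  0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
}

#' Per-component likelihood-ratio p-values
#'
#' Refits the model dropping each kernel in turn and applies
#' [component_pvalue()].
#'
#' @param fit a `holo_vcfit` with at least one kernel.
#' @param ... passed to [reml_fit()] for the reduced fits.
#' @return named vector of p-values, one per kernel.
#' @export
component_pvalues <- function(fit, ...) {
  kn <- names(fit$kernels)
  vapply(kn, function(nm) {
    reduced_kernels <- fit$kernels[setdiff(kn, nm)]
    red <- if (length(reduced_kernels)) {
      reml_fit(fit$y, fit$X, reduced_kernels, ...)
    } else {
      # null model y ~ N(X beta, sigma2 I): with the fixed effects
      # absorbed, Q'y ~ N(0, sigma2 I_{n-p}) and the restricted logL at
      # the profiled sigma2 = RSS/(n-p) has a closed form
      n <- fit$n
      p <- fit$p_fixed
      r <- stats::residuals(stats::lm.fit(fit$X, fit$y))
      s2 <- sum(r^2) / (n - p)
      logL <- -0.5 * (n - p) * (log(2 * pi) + log(s2) + 1)
      list(logLik = logL)
    }
    component_pvalue(fit, red)
  }, numeric(1))
}

#' The six microbiability covariate sets
#'
#' Builds the six candidate fixed-covariate sets screened by BIC before
#' estimating microbiability. All include body weight; they differ in
#' whether sex, the first five genome-wide principal components
#' (population structure), and the first two PCs from a trait-associated
#' SNP subset enter:
#'
#' 1. BW + 5 genomic PCs
#' 2. BW + 2 subset-SNP PCs
#' 3. BW + 5 genomic PCs + 2 subset-SNP PCs
#' 4. BW + sex + 5 genomic PCs
#' 5. BW + sex + 2 subset-SNP PCs
#' 6. BW + sex + 5 genomic PCs + 2 subset-SNP PCs
#'
#' @param bw numeric body-weight vector.
#' @param sex factor (or coercible) sex vector.
#' @param grm_pcs matrix with >= 5 columns, PCs of the genome-wide GRM
#'   ([kernel_pca()]).
#' @param subset_pcs matrix with >= 2 columns, PCs at the trait-associated
#'   SNP subset ([snp_subset_pcs()]), or NULL — then only sets 1 and 4 are
#'   returned.
#' @return named list of covariate data.frames (`set1` ... `set6`).
#' @export
covariate_sets <- function(bw, sex, grm_pcs, subset_pcs = NULL) {
  g5 <- as.data.frame(grm_pcs[, 1:5, drop = FALSE])
  names(g5) <- paste0("gPC", 1:5)
  base <- data.frame(BW = bw)
  sets <- list()
  if (!is.null(subset_pcs)) {
    s2 <- as.data.frame(subset_pcs[, 1:2, drop = FALSE])
    names(s2) <- paste0("sPC", 1:2)
    sets <- list(set1 = cbind(base, g5),
                 set2 = cbind(base, s2),
                 set3 = cbind(base, g5, s2),
                 set4 = cbind(base, sex = factor(sex), g5),
                 set5 = cbind(base, sex = factor(sex), s2),
                 set6 = cbind(base, sex = factor(sex), g5, s2))
  } else {
    message("no subset-SNP PCs supplied; only covariate sets 1 and 4 available")
    sets <- list(set1 = cbind(base, g5),
                 set4 = cbind(base, sex = factor(sex), g5))
  }
  sets
}

#' Select the covariate set with minimal BIC
#'
#' Fits the single-kernel model under each candidate covariate set and
#' keeps the set with the smallest `BIC = k ln(n) - 2 ln(L)`; ties are
#' broken in favour of fewer parameters. Sets whose design is rank
#' deficient are skipped with a warning.
#'
#' @param y trait vector.
#' @param sets named list of covariate data.frames ([covariate_sets()]).
#' @param kernel the random-effect kernel (MRM for microbiability).
#' @param ... passed to [reml_fit()].
#' @return list: `best` (set name), `fit` (the winning `holo_vcfit`),
#'   `table` (per-set k, logLik, BIC, variance ratio).
#' @export
select_covariates <- function(y, sets, kernel, ...) {
  fits <- list()
  rows <- list()
  for (nm in names(sets)) {
    fit <- tryCatch(
      fit_single_kernel(y, sets[[nm]], kernel, "m", ...),
      error = function(e) {
        warning(sprintf("covariate set %s skipped: %s", nm,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(set = nm, k = fit$k_params,
                             logLik = fit$logLik, bic = fit$bic,
                             ratio = fit$ratio,
                             stringsAsFactors = FALSE)
  }
  if (!length(fits))
    stop_hologreml("no covariate set could be fitted",
                   "hologreml_validation_error")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(tab$bic, tab$k)
  best <- tab$set[ord[1]]
  list(best = best, fit = fits[[best]], table = tab)
}
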