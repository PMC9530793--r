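test_that("single-kernel REML recovers a known variance fraction", {
  K <- make_structured_kernel(300, r = 50, seed = 99)
  # one fixed replicate
  y <- draw_kernel_trait(K, 0.5, seed = 1)
  fit <- reml_fit(y, NULL, list(g = K))
  expect_lt(abs(fit$fractions["g"] - 0.5), 0.15)
  expect_true(fit$converged)
  # mean over 50 replicates is close to the truth
  est <- vapply(1:50, function(s)
    reml_fit(draw_kernel_trait(K, 0.5, seed = s), NULL,
             list(g = K))$fractions[["g"]], numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("pure-noise traits give near-zero kernel fractions", {
  K <- make_structured_kernel(300, r = 50, seed = 99)
  set.seed(77)
  frac <- vapply(1:100, function(s)
    reml_fit(rnorm(300), NULL, list(g = K))$fractions[["g"]], numeric(1))
  expect_gte(mean(frac < 0.1), 0.9)
})

test_that("AI-REML reaches at least the grid-search likelihood on small fixtures", {
  for (s in 1:5) {
    K <- make_structured_kernel(60, r = 15, seed = 100 + s)
    y <- draw_kernel_trait(K, c(0.2, 0.35, 0.5, 0.65, 0.8)[s], seed = 200 + s)
    ai <- reml_fit(y, NULL, list(g = K))
    grid <- reml_fit(y, NULL, list(g = K), algorithm = "grid")
    expect_gte(ai$logLik, grid$logLik - 1e-4)
  }
})

test_that("REML estimates are invariant to shifting y and equivariant to rescaling", {
  K <- make_structured_kernel(120, r = 30, seed = 55)
  y <- draw_kernel_trait(K, 0.4, seed = 5)
  f0 <- reml_fit(y, NULL, list(g = K))
  f_shift <- reml_fit(y + 100, NULL, list(g = K))
  f_scale <- reml_fit(y * 3, NULL, list(g = K))
  expect_equal(f_shift$fractions, f0$fractions, tolerance = 1e-6)
  expect_equal(f_scale$fractions, f0$fractions, tolerance = 1e-6)
  expect_equal(f_scale$components, f0$components * 9, tolerance = 1e-4)
})

test_that("REML is invariant to a consistent permutation of individuals", {
  set.seed(66)
  sim <- simulate_hologenome(sim_config(n_individuals = 80, n_snps = 200,
                                        n_otus = 80, seed = 6))
  y <- sim$pheno$trait
  X <- stats::model.matrix(~ sex + BW, sim$pheno)
  Ks <- lapply(sim$kernels, function(k) k$K)
  f0 <- suppressWarnings(reml_fit(y, X, Ks))
  perm <- sample(80)
  f1 <- suppressWarnings(reml_fit(y[perm], X[perm, ],
                                  lapply(Ks, function(K) K[perm, perm])))
  expect_equal(f1$fractions, f0$fractions, tolerance = 1e-8)
  expect_equal(f1$logLik, f0$logLik, tolerance = 1e-8)
})

test_that("an identity kernel leaves the decomposition unidentifiable and is flagged", {
  set.seed(67)
  fit <- suppressWarnings(reml_fit(rnorm(60), NULL, list(g = diag(60))))
  expect_false(fit$identifiable)
  expect_true(all(is.na(fit$se_fractions)))
})

test_that("variance fractions reproduce the worked leaf-fat decomposition", {
  tab <- variance_fractions(c(g = 1.54, m = 0.19, a = 0.26, e = 0.00))
  expect_equal(tab$fraction_2dp[1:3], c(0.77, 0.10, 0.13))
  expect_equal(sum(tab$fraction), 1)
  # single component owns the whole variance
  expect_equal(variance_fractions(c(g = 2.2))$fraction, 1)
  expect_error(variance_fractions(c(g = 0, e = 0)),
               class = "hologreml_validation_error")
})

test_that("boundary-mixture likelihood-ratio p-values follow the chi-square evaluation", {
  f_full <- list(logLik = -100)
  expect_equal(component_pvalue(f_full, list(logLik = -100)), 0.5)
  expect_equal(component_pvalue(list(logLik = -100 + 2.706 / 2),
                                list(logLik = -100)),
               0.5 * stats::pchisq(2.706, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(component_pvalue(list(logLik = -100 + 2.706 / 2),
                                list(logLik = -100)), 0.05, tolerance = 1e-3)
  expect_warning(component_pvalue(list(logLik = -101), list(logLik = -100)),
                 "refit")
})

test_that("the boundary-mixture test is calibrated under the null", {
  n <- 120
  K <- make_structured_kernel(n, r = 30, seed = 88)
  set.seed(303)
  rej <- vapply(1:500, function(i) {
    y <- rnorm(n)
    fit <- reml_fit(y, NULL, list(g = K))
    component_pvalues(fit)[["g"]] < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)
})

test_that("BIC follows k ln(n) - 2 ln(L) including the k = 0 boundary", {
  expect_equal(bic_value(-150, 0, 100), 300)
  expect_equal(bic_value(-100, 2, 239), 2 * log(239) + 200)
  expect_equal(bic_value(-100, 2, 239), 210.953, tolerance = 1e-3)
})

test_that("the six covariate sets are built as specified and degrade to two without subset PCs", {
  n <- 50
  pcs <- matrix(rnorm(n * 5), n)
  spcs <- matrix(rnorm(n * 2), n)
  sex <- rep_len(c("M", "F"), n)
  bw <- rnorm(n, 100, 10)
  sets <- covariate_sets(bw, sex, pcs, spcs)
  expect_named(sets, paste0("set", 1:6))
  expect_named(sets$set1, c("BW", paste0("gPC", 1:5)))
  expect_named(sets$set2, c("BW", "sPC1", "sPC2"))
  expect_named(sets$set6, c("BW", "sex", paste0("gPC", 1:5), "sPC1", "sPC2"))
  expect_false("sex" %in% names(sets$set3))
  sets14 <- suppressMessages(covariate_sets(bw, sex, pcs, NULL))
  expect_named(sets14, c("set1", "set4"))
})

test_that("BIC selection prefers covariate sets containing a real effect", {
  set.seed(404)
  n <- 150
  K <- make_structured_kernel(n, r = 40, seed = 21)
  pcs <- matrix(rnorm(n * 5), n)
  spcs <- matrix(rnorm(n * 2), n)
  sex <- factor(rep_len(c("M", "F"), n))
  bw <- rnorm(n, 100, 10)
  sets <- covariate_sets(bw, sex, pcs, spcs)
  wins <- vapply(1:30, function(i) {
    y <- 0.9 * (sex == "M") + 0.02 * bw +
      draw_kernel_trait(K, 0.3, seed = 500 + i)
    sel <- select_covariates(y, sets, K)
    sel$best %in% c("set4", "set5", "set6")
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("heritability and microbiability wrappers expose the single-kernel ratio", {
  sim <- simulate_hologenome(sim_config(n_individuals = 150, n_snps = 600,
                                        n_otus = 150,
                                        fractions = c(g = 0, m = 0.5, a = 0, e = 0.5),
                                        seed = 31))
  cov <- data.frame(sex = sim$pheno$sex, BW = sim$pheno$BW)
  m2 <- microbiability(sim$pheno$trait, cov, sim$kernels$m)
  expect_s3_class(m2, "holo_vcfit")
  expect_true(m2$ratio >= 0 && m2$ratio <= 1)
  expect_equal(unname(m2$fractions["m"]), m2$ratio)
  h2 <- heritability(sim$pheno$trait, cov, sim$kernels$g)
  expect_lt(h2$ratio, m2$ratio)   # trait is microbiome-driven here
})

test_that("microbiability is near zero when the simulated microbial effect is absent", {
  rate <- vapply(1:30, function(s) {
    sim <- simulate_hologenome(sim_config(n_snps = 1000,
                                          fractions = c(g = 0.5, m = 0, a = 0, e = 0.5),
                                          seed = 600 + s))
    cov <- data.frame(sex = sim$pheno$sex, BW = sim$pheno$BW)
    suppressMessages(microbiability(sim$pheno$trait, cov,
                                    sim$kernels$m))$ratio < 0.1
  }, logical(1))
  expect_gte(mean(rate), 0.9)
})

test_that("rank-deficient fixed designs are rejected", {
  K <- make_structured_kernel(40, r = 10, seed = 2)
  X <- cbind(1, rep(1, 40))
  expect_error(suppressWarnings(reml_fit(rnorm(40), X, list(g = K))),
               class = "hologreml_validation_error")
})
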