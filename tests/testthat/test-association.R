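test_that("exact Wilcoxon p matches the fully separated three-vs-three case", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6, mode = "exact"), 0.1,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5)), 1)
})

test_that("exact mode equals full enumeration for all tie-free shapes with n <= 10", {
  set.seed(51)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    vals <- sample(seq(0.01, 1, length.out = 50), n1 + n2)
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact"),
                 wilcoxon_enum_p(x, y), tolerance = 1e-10,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("normal approximation stays within 0.05 of the exact p for groups of three or more", {
  # every rank configuration, not just random draws; singleton and pair
  # groups are excluded — there the normal approximation can be off by up
  # to ~0.13 and only the exact mode is trustworthy
  for (n1 in 3:5) for (n2 in n1:(10 - n1)) {
    combos <- utils::combn(n1 + n2, n1)
    for (j in seq_len(ncol(combos))) {
      x <- (1:(n1 + n2))[combos[, j]]
      y <- (1:(n1 + n2))[-combos[, j]]
      expect_lt(abs(wilcoxon_rank_sum(x, y, mode = "normal") -
                    wilcoxon_enum_p(x, y)), 0.05)
    }
  }
})

test_that("divergent groups use nearest-half-up rounding and stay disjoint", {
  set.seed(53)
  g239 <- divergent_groups(rnorm(239), 0.2)
  expect_equal(g239$size, 48)
  v <- c(10, 3, 8, 1, 9, 2, 7, 4, 6, 5)
  g10 <- divergent_groups(v, 0.2)
  expect_equal(g10$size, 2)
  expect_setequal(g10$high, which(v >= 9))
  expect_setequal(g10$low, which(v <= 2))
  expect_length(intersect(g10$high, g10$low), 0)
  # shuffled input yields identical membership
  vals <- rnorm(100)
  perm <- sample(100)
  g1 <- divergent_groups(vals, 0.2)
  g2 <- divergent_groups(vals[perm], 0.2)
  expect_setequal(perm[g2$high], g1$high)
  expect_setequal(perm[g2$low], g1$low)
  expect_error(divergent_groups(rnorm(3), 0.5),
               class = "hologreml_validation_error")
  # all-tied values still produce disjoint groups
  gt <- divergent_groups(rep(1, 10), 0.2)
  expect_length(intersect(gt$high, gt$low), 0)
})

test_that("a perfectly monotone genus is flagged in both scan directions", {
  set.seed(54)
  n <- 100
  trait <- sort(rnorm(n))
  ab <- matrix(0, 2, n)
  ab[1, ] <- seq(0.01, 0.2, length.out = n)   # abundance = trait rank
  ab[2, ] <- 1 - ab[1, ]
  gp <- structure(list(abundance = ab, genera = c("mono", "anti"),
                       individual_ids = sprintf("i%03d", 1:n),
                       mean_abundance = rowMeans(ab)),
                  class = "holo_genus")
  res <- divergent_scan(trait, gp)
  expect_true(res$significant_both[res$genus == "mono"])
  expect_lt(res$p_trait_m[1], 0.05)
  expect_lt(res$p_m_trait[1], 0.05)
})

test_that("divergent scan is symmetric under trait negation", {
  set.seed(55)
  n <- 80
  trait <- rnorm(n)
  ab <- matrix(rexp(5 * n), 5)
  ab <- sweep(ab, 2, colSums(ab), "/")
  gp <- structure(list(abundance = ab, genera = paste0("G", 1:5),
                       individual_ids = sprintf("i%03d", 1:n),
                       mean_abundance = rowMeans(ab)),
                  class = "holo_genus")
  r1 <- divergent_scan(trait, gp)
  r2 <- divergent_scan(-trait, gp)
  expect_equal(r2$p_trait_m, r1$p_trait_m, tolerance = 1e-12)
  expect_equal(r2$p_m_trait, r1$p_m_trait, tolerance = 1e-12)
  # high/low trait groups swap
  expect_equal(r2$micro_mean_high_trait, r1$micro_mean_low_trait)
})

test_that("a constant genus gets p = 1 in both directions and a flag", {
  n <- 60
  trait <- rnorm(n)
  ab <- rbind(rep(0.5, n), runif(n))
  gp <- structure(list(abundance = ab, genera = c("const", "varies"),
                       individual_ids = sprintf("i%03d", 1:n),
                       mean_abundance = rowMeans(ab)),
                  class = "holo_genus")
  res <- divergent_scan(trait, gp)
  expect_true(res$constant[1])
  expect_equal(res$p_trait_m[1], 1)
  expect_equal(res$p_m_trait[1], 1)
  expect_false(res$significant_both[1])
})

test_that("double-significance under the null is far rarer than a single 5% test", {
  # the two directional p-values share the same underlying genus-trait
  # association (log-p correlation ~0.6), so the joint rate sits near
  # 1.5-2% — well below 5%, though not as low as independence would give
  set.seed(56)
  n <- 239
  trait <- rnorm(n)
  ab <- matrix(rexp(1000 * n), 1000)
  ab <- sweep(ab, 2, colSums(ab), "/")
  gp <- structure(list(abundance = ab, genera = paste0("G", 1:1000),
                       individual_ids = sprintf("i%03d", 1:n),
                       mean_abundance = rowMeans(ab)),
                  class = "holo_genus")
  res <- divergent_scan(trait, gp)
  expect_lte(mean(res$significant_both), 0.03)
})

test_that("association scan without kinship reduces to simple linear regression", {
  set.seed(57)
  n <- 90
  ab <- matrix(rexp(n), 1)
  ab <- ab / sum(ab) # one genus, one row
  ab <- matrix(runif(n, 0.001, 0.02), 1)
  trait <- 5 + 20 * ab[1, ] + rnorm(n)
  gp <- structure(list(abundance = ab, genera = "G1",
                       individual_ids = sprintf("i%03d", 1:n),
                       mean_abundance = rowMeans(ab)),
                  class = "holo_genus")
  res <- mwas_scan(trait, gp, covariates = NULL, kinship = NULL)
  lmfit <- summary(stats::lm(trait ~ ab[1, ]))
  expect_equal(res$beta, unname(lmfit$coefficients[2, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(lmfit$coefficients[2, 4]), tolerance = 1e-8)
  expect_equal(res$F, unname(lmfit$coefficients[2, 3])^2, tolerance = 1e-8)
})

test_that("association p-values are invariant to affine rescaling of abundance", {
  set.seed(58)
  n <- 100
  ab <- matrix(runif(2 * n, 0.001, 0.05), 2)
  trait <- rnorm(n) + 5 * ab[1, ]
  cov <- data.frame(sex = factor(rep_len(c("M", "F"), n)), BW = rnorm(n, 100, 10))
  gp <- structure(list(abundance = ab, genera = c("G1", "G2"),
                       individual_ids = sprintf("i%03d", 1:n),
                       mean_abundance = rowMeans(ab)),
                  class = "holo_genus")
  gp2 <- gp
  gp2$abundance <- ab * 100
  r1 <- mwas_scan(trait, gp, cov, kinship = NULL)
  r2 <- mwas_scan(trait, gp2, cov, kinship = NULL)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
  expect_equal(r2$beta, r1$beta / 100, tolerance = 1e-10)
})

test_that("association scan detects a genus explaining 10% of trait variance", {
  n <- 239
  set.seed(59)
  ab_base <- matrix(runif(n, 0.001, 0.05), 1)
  hits <- vapply(1:100, function(i) {
    g <- scale(ab_base[1, ])[, 1]
    y <- sqrt(0.1) * g + rnorm(n, 0, sqrt(0.9))
    gp <- structure(list(abundance = ab_base, genera = "G1",
                         individual_ids = sprintf("i%03d", 1:n),
                         mean_abundance = rowMeans(ab_base)),
                    class = "holo_genus")
    mwas_scan(y, gp, covariates = NULL, kinship = NULL)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("mixed-model scan with a polygenic kernel controls structured confounding", {
  set.seed(60)
  n <- 150
  K <- make_structured_kernel(n, r = 10, seed = 61)
  u <- draw_kernel_trait(K, 0.99, seed = 62)      # strongly structured trait
  ab <- matrix(runif(3 * n, 0.001, 0.05), 3)
  gp <- structure(list(abundance = ab, genera = paste0("G", 1:3),
                       individual_ids = sprintf("i%03d", 1:n),
                       mean_abundance = rowMeans(ab)),
                  class = "holo_genus")
  res <- mwas_scan(u, gp, covariates = NULL,
                   kinship = kernel_matrix(K, sprintf("i%03d", 1:n)))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_equal(res$n_used, rep(n, 3))
})

test_that("candidate intersection requires significance in both screens", {
  div <- data.frame(genus = c("A", "B", "C"),
                    significant_both = c(TRUE, FALSE, TRUE))
  mwas <- data.frame(genus = c("A", "B", "C"), p = c(0.01, 0.01, 0.2))
  expect_equal(candidate_intersection(div, mwas), "A")
  expect_length(candidate_intersection(div[0, ], mwas[0, ]), 0)
  mwas$p <- c(0.5, 0.5, 0.5)
  expect_length(candidate_intersection(div, mwas), 0)
})
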