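test_that("IBS kinship matches a per-pair loop and handles edge values", {
  g <- rbind(a = c(0, 0, 2, 2), b = c(0, 0, 2, 2), c = c(2, 2, 0, 0))
  colnames(g) <- paste0("m", 1:4)
  K <- ibs_kinship(g)
  expect_equal(K["a", "b"], 1)
  expect_equal(K["a", "c"], 0)

  gr <- random_genotypes(4, 10, 30, miss = 0.1, codes = c(0, 1, 2))
  expect_equal(ibs_kinship(gr), oracle_ibs(gr), tolerance = 1e-12)

  gs <- gr
  gs[1, ] <- NA; gs[1, 1] <- 0
  gs[2, ] <- NA; gs[2, 2] <- 0
  expect_error(ibs_kinship(gs), class = "qgscan_sparsity_error")
})

test_that("with identity kinship the mixed model reduces to ordinary regression", {
  set.seed(5)
  n <- 40
  x <- rbinom(n, 1, 0.5) * 2
  y <- 0.3 * x / 2 + rnorm(n)
  X <- cbind(1, x / 2)
  K <- diag(n)
  fit <- suppressWarnings(emma_reml_fit(y, X, K))
  ols <- summary(lm(y ~ I(x / 2)))$coefficients
  expect_equal(unname(fit$beta[2]), ols[2, 1], tolerance = 1e-9)
  expect_equal(unname(fit$t[2]), ols[2, 3], tolerance = 1e-9)
  expect_equal(unname(fit$p[2]), ols[2, 4], tolerance = 1e-9)
})

test_that("REML delta matches a 2001-point dense grid oracle on structured data", {
  set.seed(7)
  panel <- small_panel(seed = 70, n = 60, fst = 0.2)
  K <- ibs_kinship(panel$genotypes)
  n <- nrow(K)
  ## simulate y with delta = 1: Var = sigma_g2 (K + I)
  L <- chol(K + diag(n) + diag(1e-8, n))
  y <- drop(crossprod(L, rnorm(n))) + 1
  X <- matrix(1, n, 1)
  fit <- suppressWarnings(emma_reml_fit(y, X, K))  # boundary fits can warn
  oracle <- oracle_reml_grid(y, X, K)
  expect_lte(abs(log10(fit$delta) - log10(oracle$delta)), oracle$step_log10)
  expect_gte(fit$reml_loglik, oracle$loglik - 1e-8)
})

test_that("the restricted likelihood is invariant to joint strain relabeling", {
  set.seed(8)
  panel <- small_panel(seed = 71, n = 40, fst = 0.2)
  K <- ibs_kinship(panel$genotypes)
  n <- nrow(K)
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  f1 <- suppressWarnings(emma_reml_fit(y, X, K))
  pm <- sample(n)
  f2 <- suppressWarnings(emma_reml_fit(y[pm], X[pm, ], K[pm, pm]))
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-9)
  expect_equal(f1$delta, f2$delta, tolerance = 1e-6)
})

test_that("scan p-values equal per-marker regression under identity kinship", {
  g <- random_genotypes(9, 40, 25)
  K <- diag(nrow(g)); dimnames(K) <- list(rownames(g), rownames(g))
  set.seed(10)
  y <- stats::setNames(rnorm(nrow(g)), rownames(g))
  scan <- emma_scan(y, g, K, min_maf = 0.05)
  for (j in which(scan$tested)) {
    ols <- summary(lm(y ~ I(g[, j] / 2)))$coefficients
    expect_equal(scan$p[j], ols[2, 4], tolerance = 1e-9)
  }
  ## zero-variance marker flagged untested
  g2 <- g; g2[, 1] <- 0
  scan2 <- emma_scan(y, g2, K)
  expect_false(scan2$tested[1])
})

test_that("scan p-values are invariant to affine phenotype rescaling", {
  panel <- small_panel(seed = 33, n = 50, fst = 0.15)
  K <- ibs_kinship(panel$genotypes)
  set.seed(11)
  y <- stats::setNames(rnorm(50), rownames(panel$genotypes))
  s1 <- emma_scan(y, panel$genotypes, K)
  s2 <- emma_scan(3.7 * y - 1.2, panel$genotypes, K)
  expect_equal(s1$p[s1$tested], s2$p[s2$tested], tolerance = 1e-9)
})

test_that("null p-values are approximately uniform (KS check across scans)", {
  panel <- small_panel(seed = 51, n = 50, fst = 0.1, chroms = c(I = 60),
                       mpc = 60)
  K <- ibs_kinship(panel$genotypes)
  n_pass <- 0
  n_scan <- 60
  for (i in seq_len(n_scan)) {
    set.seed(1000 + i)
    y <- stats::setNames(rnorm(50), rownames(panel$genotypes))
    sc <- emma_scan(y, panel$genotypes, K)
    p <- sc$p[sc$tested]
    ks <- max(abs(sort(p) - (seq_along(p) - 0.5) / length(p))) +
      0.5 / length(p)
    crit <- 1.628 / (sqrt(length(p)) + 0.12 + 0.11 / sqrt(length(p)))
    if (ks < crit) n_pass <- n_pass + 1
  }
  expect_gte(n_pass / n_scan, 0.95)
})

test_that("permutation FDR is zero for a dominant signal and monotone in p", {
  panel <- small_panel(seed = 61, n = 60, fst = 0.1)
  j <- 10
  set.seed(12)
  y <- stats::setNames(panel$genotypes[, j] / 2 + rnorm(60, 0, 0.3),
                       rownames(panel$genotypes))
  K <- ibs_kinship(panel$genotypes)
  scan <- emma_scan(y, panel$genotypes, K)
  fdr <- permutation_fdr(scan, y, panel$genotypes, K, n_permutations = 150,
                         seed = 4)
  top <- fdr$table[which.min(fdr$table$p), ]
  expect_lte(top$fdr, 0.05)
  expect_true(all(diff(fdr$thresholds$fdr) >= -1e-12))
  expect_true(all(fdr$table$fdr >= 0 & fdr$table$fdr <= 1))
  ## determinism under a fixed seed
  fdr2 <- permutation_fdr(scan, y, panel$genotypes, K, n_permutations = 150,
                          seed = 4)
  expect_identical(fdr$table, fdr2$table)
  expect_error(permutation_fdr(scan, y, panel$genotypes, K,
                               n_permutations = 50),
               class = "qgscan_config_error")
})

test_that("a strong simulated QTL is found at or near the top of the scan", {
  hits <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    panel <- small_panel(seed = 400 + i, n = 100, fst = 0.1,
                         chroms = c(I = 50, II = 50), mpc = 25)
    j <- 12
    dose <- panel$genotypes[, j] / 2
    ## effect sized for ~20% of phenotypic variance
    b <- sqrt(0.2 / 0.8) * 1 / stats::sd(dose)
    set.seed(i)
    y <- stats::setNames(b * dose + rnorm(100), rownames(panel$genotypes))
    K <- ibs_kinship(panel$genotypes)
    sc <- emma_scan(y, panel$genotypes, K)
    topj <- which.min(sc$p)
    r2 <- suppressWarnings(cor(panel$genotypes[, topj],
                               panel$genotypes[, j]))^2
    if (topj == j || (is.finite(r2) && r2 > 0.8)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("kinship correction controls structure-driven inflation better than OLS", {
  wins <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    panel <- small_panel(seed = 800 + i, n = 60, fst = 0.3, subpops = 2,
                         chroms = c(I = 50, II = 50), mpc = 30)
    arch <- trait_architecture(baseline = c(trait1 = 0),
                               polygenic_n_loci = 40, polygenic_sd = 1,
                               strain_sd = 0.2)
    ph <- simulate_phenotypes(panel$genotypes, panel$map, arch, seed = 900 + i)
    y <- qlogis(pmin(pmax(trait_vector(ph, "trait1"), 1e-4), 1 - 1e-4))
    K <- ibs_kinship(panel$genotypes)
    sc <- emma_scan(y, panel$genotypes, K)
    chi_mm <- qchisq(sc$p[sc$tested], df = 1, lower.tail = FALSE)
    p_ols <- apply(panel$genotypes[, sc$tested, drop = FALSE], 2, function(gj) {
      summary(lm(y ~ gj))$coefficients[2, 4]
    })
    chi_ols <- qchisq(p_ols, df = 1, lower.tail = FALSE)
    lam_mm <- median(chi_mm) / qchisq(0.5, 1)
    lam_ols <- median(chi_ols) / qchisq(0.5, 1)
    if (abs(lam_mm - 1) < abs(lam_ols - 1)) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.95)
})
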