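test_that("allelic effects are differences of class medians", {
  g <- matrix(c(0, 0, 0, 2, 2, 2), 6, 1,
              dimnames = list(paste0("s", 1:6), "m1"))
  y1 <- stats::setNames(c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60), rownames(g))
  y2 <- stats::setNames(rep(0.25, 6), rownames(g))
  tab <- per_snp_allelic_effect(g, y1, y2, min_class_size = 3)
  expect_equal(tab$effect_trait1, 0.50 - 0.20)
  expect_equal(tab$effect_trait2, 0)           # constant phenotype
  expect_true(tab$included)

  ## random fixture vs a direct group-by-median oracle
  gr <- random_genotypes(21, 30, 25)
  set.seed(22)
  p1 <- stats::setNames(runif(30), rownames(gr))
  p2 <- stats::setNames(runif(30), rownames(gr))
  tab2 <- per_snp_allelic_effect(gr, p1, p2, min_class_size = 3)
  for (j in seq_len(ncol(gr))) {
    ref <- p1[gr[, j] == 0]; alt <- p1[gr[, j] == 2]
    if (length(ref) >= 3 && length(alt) >= 3) {
      expect_equal(tab2$effect_trait1[j], median(alt) - median(ref),
                   tolerance = 1e-12)
    } else {
      expect_identical(tab2$reason[j], "class_size")
    }
  }
})

test_that("markers with a single genotype class are excluded, not an error", {
  g <- cbind(m1 = rep(0, 8), m2 = c(0, 0, 0, 0, 2, 2, 2, 2))
  rownames(g) <- paste0("s", 1:8)
  y <- stats::setNames(runif(8), rownames(g))
  tab <- per_snp_allelic_effect(g, y, y, min_class_size = 3)
  expect_false(tab$included[1])
  expect_identical(tab$reason[1], "class_size")
  expect_true(tab$included[2])
})

test_that("LD pruning keeps one survivor per duplicate chain and all independent markers", {
  set.seed(23)
  base <- sample(c(0, 2), 40, replace = TRUE)
  g_dup <- matrix(rep(base, 6), 40, 6,
                  dimnames = list(paste0("s", 1:40), paste0("m", 1:6)))
  kept <- ld_prune(g_dup, window_size = 6, step = 2, r2_threshold = 0.8)
  expect_length(kept, 1)

  g_ind <- random_genotypes(24, 200, 10)
  kept2 <- ld_prune(g_ind, window_size = 10, step = 3, r2_threshold = 0.8)
  expect_length(kept2, 10)
  expect_error(ld_prune(g_ind, window_size = 1), class = "qgscan_config_error")
})

test_that("windowed pruning equals an exhaustive greedy oracle with the same tie rules", {
  set.seed(25)
  n <- 60
  g <- matrix(NA_real_, n, 20)
  g[, 1] <- sample(c(0, 2), n, replace = TRUE)
  for (j in 2:20) {
    flip <- runif(n) < 0.12
    g[, j] <- ifelse(flip, 2 - g[, j - 1], g[, j - 1])
  }
  dimnames(g) <- list(paste0("s", 1:n), sprintf("m%02d", 1:20))
  kept <- ld_prune(g, window_size = 8, step = 3, r2_threshold = 0.7)
  expect_identical(as.character(kept),
                   oracle_ld_prune(g, 8, 3, 0.7))
})

test_that("z-score outlier removal is a single pass with the stated arithmetic", {
  mk_tab <- function(e1) {
    g <- matrix(rep(c(0, 0, 0, 2, 2, 2), length(e1)), 6, length(e1),
                dimnames = list(paste0("s", 1:6),
                                sprintf("m%02d", seq_along(e1))))
    y1 <- stats::setNames(c(0, 0, 0, 0, 0, 0), rownames(g))
    tab <- per_snp_allelic_effect(g, y1, y1, min_class_size = 3)
    tab$effect_trait1 <- e1
    tab$effect_trait2 <- 0 * e1
    tab
  }
  ## effects (0, 0, 0, 10): sd = 5, max |z| = 1.5 -> nothing removed
  t1 <- suppressWarnings(zscore_outlier_filter(mk_tab(c(0, 0, 0, 10))))
  expect_true(all(t1$included))
  ## twenty 0s and one 10: z ~ 4.37 -> removed
  t2 <- suppressWarnings(zscore_outlier_filter(mk_tab(c(rep(0, 20), 10))))
  expect_false(t2$included[21])
  expect_identical(t2$reason[21], "outlier")
  expect_equal(sum(!t2$included), 1)
  ## zero-variance effects: warning, no removals (trait2 is constant here,
  ## trait1 varies below its cutoff)
  expect_warning(t3 <- zscore_outlier_filter(mk_tab(c(1, 2, 3, 4, 5))),
                 "zero variance")
  expect_true(all(t3$included))
})

test_that("cross-trait correlation hits exact values and flags small groups", {
  g <- random_genotypes(26, 40, 12)
  set.seed(27)
  p1 <- stats::setNames(runif(40), rownames(g))
  p2 <- stats::setNames(runif(40), rownames(g))
  map <- data.frame(marker = colnames(g),
                    chrom = rep(c("I", "II"), c(10, 2)),
                    bp = seq_len(12), cM = seq_len(12))
  tab <- per_snp_allelic_effect(g, p1, p2, min_class_size = 3, map = map)
  tab$effect_trait2 <- -tab$effect_trait1
  rep <- cross_trait_correlation(tab)
  expect_equal(rep$genome$R, -1, tolerance = 1e-12)
  ## the two-marker chromosome II group is undefined, not an error
  ii <- rep$by_chrom[rep$by_chrom$chrom == "II", ]
  expect_true(ii$undefined)
  expect_true(is.na(ii$R))
  ## stage counts never increase along the chain
  expect_true(all(diff(rep$stage_counts) <= 0))
})

test_that("flipping the reference labeling negates effects but not the correlation", {
  g <- random_genotypes(28, 50, 15)
  set.seed(29)
  p1 <- stats::setNames(runif(50), rownames(g))
  p2 <- stats::setNames(runif(50), rownames(g))
  t1 <- per_snp_allelic_effect(g, p1, p2, min_class_size = 3)
  t2 <- per_snp_allelic_effect(2 - g, p1, p2, min_class_size = 3)
  inc <- t1$included & t2$included
  expect_equal(t1$effect_trait1[inc], -t2$effect_trait1[inc], tolerance = 1e-12)
  r1 <- cross_trait_correlation(t1)
  r2 <- cross_trait_correlation(t2)
  expect_equal(r1$genome$R, r2$genome$R, tolerance = 1e-12)
})

test_that("strain-level Spearman handles monotone, anti-monotone and tied data", {
  y1 <- stats::setNames(1:10 / 10, paste0("s", 1:10))
  y2 <- stats::setNames((1:10)^2 / 100, paste0("s", 1:10))
  expect_equal(strain_level_correlation(y1, y2)$rho, 1)
  expect_equal(strain_level_correlation(y1, stats::setNames(rev(y2), names(y2)))$rho, -1)

  set.seed(30)
  yt <- stats::setNames(sample(c(0.2, 0.4, 0.4, 0.6, 0.6, 0.6, 0.8, 1, 0.2, 0.4)),
                        paste0("s", 1:10))
  got <- strain_level_correlation(y1, yt)
  r1 <- rank(y1); r2 <- rank(yt[names(y1)])
  rho_oracle <- cor(r1, r2)
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  tt <- rho_oracle * sqrt(8 / (1 - rho_oracle^2))
  expect_equal(got$p, 2 * pt(-abs(tt), 8), tolerance = 1e-12)

  expect_error(strain_level_correlation(y1[1:3], y2[1:3]),
               class = "qgscan_sample_size_error")
})

test_that("independent trait architectures give correlations centered on zero", {
  Rs <- numeric(30)
  for (i in seq_len(30)) {
    panel <- small_panel(seed = 3000 + i, n = 60, fst = 0, subpops = 1,
                         chroms = c(I = 80), mpc = 20)
    par <- parents_for(panel$map)
    g <- simulate_ril_population(par$a, par$b, panel$map, 80, 10,
                                 seed = 3100 + i)
    set.seed(3200 + i)
    p1 <- stats::setNames(runif(80), rownames(g))
    p2 <- stats::setNames(runif(80), rownames(g))
    tab <- per_snp_allelic_effect(g, p1, p2, min_class_size = 3)
    tab <- suppressWarnings(zscore_outlier_filter(tab))
    Rs[i] <- cross_trait_correlation(tab)$genome$R
  }
  expect_lt(abs(mean(Rs)), 0.15)
})
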