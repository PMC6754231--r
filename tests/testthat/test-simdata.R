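test_that("isolate panels are homozygous, deterministic, and respect the fst limit", {
  panel <- small_panel(seed = 11, miss = 0.05)
  expect_true(all(panel$genotypes %in% c(0, 2) | is.na(panel$genotypes)))
  expect_true(all(diff(panel$map$cM[panel$map$chrom == "I"]) >= 0))

  panel2 <- small_panel(seed = 11, miss = 0.05)
  expect_identical(panel$genotypes, panel2$genotypes)
  expect_identical(panel$map, panel2$map)

  ## fst = 0: subpopulation frequencies coincide with the ancestral ones,
  ## so the two subpanels are statistically indistinguishable
  p0 <- simulate_isolate_panel(sim_config(
    seed = 5, n_strains = 2000, chromosomes = c(I = 100),
    markers_per_chromosome = 100, n_subpopulations = 2, fst = 0))
  f <- abs(oracle_hudson_fst(p0$genotypes, p0$subpop))
  expect_lt(f, 0.01)
})

test_that("Balding-Nichols differentiation matches its target", {
  p <- simulate_isolate_panel(sim_config(
    seed = 9, n_strains = 5000, chromosomes = c(I = 100),
    markers_per_chromosome = 200, n_subpopulations = 2, fst = 0.2))
  f <- oracle_hudson_fst(p$genotypes, p$subpop)
  expect_gt(f, 0.16)
  expect_lt(f, 0.24)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(fst = 1), class = "qgscan_config_error")
  expect_error(sim_config(fst = -0.1), class = "qgscan_config_error")
  expect_error(sim_config(chromosomes = numeric(0)), class = "qgscan_config_error")
  expect_error(sim_config(markers_per_chromosome = 1), class = "qgscan_config_error")
})

test_that("RIL simulation enforces homozygous distinct parents", {
  panel <- small_panel(seed = 2, n = 4, fst = 0, subpops = 1)
  par <- parents_for(panel$map)
  bad_het <- par$a; bad_het[3] <- 1
  expect_error(simulate_ril_population(bad_het, par$b, panel$map, 10),
               class = "qgscan_precondition_error")
  bad_same <- par$b; bad_same[1] <- 0
  expect_error(simulate_ril_population(par$a, bad_same, panel$map, 10),
               class = "qgscan_precondition_error")
})

test_that("a 0-cM chromosome yields intact parental haplotypes", {
  map <- data.frame(marker = paste0("m", 1:5), chrom = "Z",
                    bp = 1:5, cM = rep(0, 5))
  par <- parents_for(map)
  g <- simulate_ril_population(par$a, par$b, map, 200, 10, seed = 4)
  ## every line is constant across the chromosome: adjacent concordance 1
  expect_true(all(apply(g, 1, function(x) length(unique(x)) == 1)))
})

test_that("residual heterozygosity decays as (1/2)^(selfings+1)", {
  panel <- small_panel(seed = 21, n = 4, fst = 0, subpops = 1,
                       chroms = c(I = 100), mpc = 25)
  par <- parents_for(panel$map)
  g <- simulate_ril_population(par$a, par$b, panel$map, 2000, 10, seed = 6)
  n_loci <- length(g)                      # 50,000 genotype calls
  expect_gte(n_loci, 50000)
  p_exp <- 0.5^11
  obs <- sum(g == 1)
  ci <- qbinom(c(0.0005, 0.9995), n_loci, p_exp)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
  ## allele frequencies stay balanced
  expect_lt(abs(mean(g == 2) - 0.5), 0.02)
})

test_that("RIL recombinant fractions follow the Haldane-Waddington expansion", {
  ## marker pairs at distances giving r = 0.1 and 0.25
  d <- -50 * log(1 - 2 * c(0.1, 0.25))
  for (k in seq_along(d)) {
    map <- data.frame(marker = c("a", "b"), chrom = "c",
                      bp = c(1L, 2L), cM = c(0, d[k]))
    par <- parents_for(map)
    g <- simulate_ril_population(par$a, par$b, map, 10000, 10, seed = 30 + k)
    hom <- g[, 1] != 1 & g[, 2] != 1
    rec <- mean(g[hom, 1] != g[hom, 2])
    r <- map_to_recfrac(d[k])
    r_exp <- ril_recfrac(r)
    tol <- 4 * sqrt(r_exp * (1 - r_exp) / sum(hom))
    expect_lt(abs(rec - r_exp), tol)
  }
})

test_that("phenotypes collapse to the logistic baseline in the noise-free limit", {
  panel <- small_panel(seed = 3, n = 20, fst = 0, subpops = 1)
  arch <- trait_architecture(baseline = c(trait1 = 0.8, trait2 = -0.4),
                             strain_sd = 0, embryos_per_replicate = 2e6,
                             replicates = 1)
  ph <- simulate_phenotypes(panel$genotypes, panel$map, arch,
                            kinship_like_background = FALSE, seed = 5)
  y1 <- trait_vector(ph, "trait1"); y2 <- trait_vector(ph, "trait2")
  expect_true(all(abs(y1 - plogis(0.8)) < 2e-3))
  expect_true(all(abs(y2 - plogis(-0.4)) < 2e-3))
  ## replicate bookkeeping: value reproducible from counts
  expect_true(all(abs(ph$value - ph$n_with_gut / ph$n_scored) < 1e-12))
  expect_true(all(ph$value >= 0 & ph$value <= 1))
})

test_that("a reciprocal QTL moves the two traits in opposite directions", {
  panel <- small_panel(seed = 13, n = 300, fst = 0, subpops = 1)
  qtl <- data.frame(chrom = "I", pos_cM = 25,
                    effect_trait1 = 1, effect_trait2 = -1)
  arch <- trait_architecture(baseline = c(trait1 = 0, trait2 = 0), qtls = qtl,
                             strain_sd = 0.2)
  ph <- simulate_phenotypes(panel$genotypes, panel$map, arch, seed = 8)
  on_chr <- which(panel$map$chrom == "I")
  j <- on_chr[which.min(abs(panel$map$cM[on_chr] - 25))]
  cls <- panel$genotypes[, j]
  y1 <- trait_vector(ph, "trait1"); y2 <- trait_vector(ph, "trait2")
  expect_gt(mean(y1[cls == 2]) - mean(y1[cls == 0]), 0)
  expect_lt(mean(y2[cls == 2]) - mean(y2[cls == 0]), 0)
})

test_that("liability-scale regression recovers the simulated effect", {
  panel <- simulate_isolate_panel(sim_config(
    seed = 17, n_strains = 1000, chromosomes = c(I = 50),
    markers_per_chromosome = 20, n_subpopulations = 1, fst = 0))
  beta <- 0.8
  qtl <- data.frame(chrom = "I", pos_cM = 25, effect_trait1 = beta)
  arch <- trait_architecture(baseline = c(trait1 = 0), qtls = qtl,
                             strain_sd = 0.15,
                             embryos_per_replicate = 5000, replicates = 2)
  ph <- simulate_phenotypes(panel$genotypes, panel$map, arch, seed = 19)
  y <- qlogis(trait_vector(ph, "trait1"))
  on_chr <- which(panel$map$chrom == "I")
  j <- on_chr[which.min(abs(panel$map$cM[on_chr] - 25))]
  fit <- summary(lm(y ~ I(panel$genotypes[, j] / 2)))$coefficients
  expect_lt(abs(fit[2, 1] - beta), 3 * fit[2, 2])
})

test_that("QTLs on unknown chromosomes are a configuration error", {
  panel <- small_panel(seed = 3, n = 10, fst = 0, subpops = 1)
  arch <- trait_architecture(baseline = c(trait1 = 0),
                             qtls = data.frame(chrom = "XII", pos_cM = 1,
                                               effect_trait1 = 1))
  expect_error(simulate_phenotypes(panel$genotypes, panel$map, arch, seed = 1),
               class = "qgscan_config_error")
})

test_that("tree traits honour the lambda-scaled Brownian covariance", {
  expect_error(simulate_trait_on_tree(ape::rcoal(8), 1.5, 1),
               class = "qgscan_domain_error")
  set.seed(42)
  tree <- ape::rcoal(8)
  C <- ape::vcv(tree)
  ## lambda = 0: independent tips, per-tip variance = rate * depth
  X0 <- t(vapply(1:1500, function(i)
    simulate_trait_on_tree(tree, 0, rate = 2, seed = i), numeric(8)))
  S0 <- cov(X0)
  expect_true(all(abs(diag(S0) - 2 * diag(C)) < 0.35))
  off <- S0[upper.tri(S0)]
  expect_lt(max(abs(off)), 0.35)
  ## lambda = 1: covariance matches the shared-path-length matrix
  X1 <- t(vapply(1:1500, function(i)
    simulate_trait_on_tree(tree, 1, rate = 2, seed = 10000 + i), numeric(8)))
  expect_lt(max(abs(cov(X1) - 2 * C)), 0.45)
})
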