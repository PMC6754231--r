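# Shared fixtures: small synthetic panels and crosses built in code.

small_panel <- function(seed = 7, n = 60, fst = 0.15, subpops = 2,
                        miss = 0, chroms = c(I = 50, II = 60), mpc = 30) {
  simulate_isolate_panel(sim_config(
    seed = seed, n_strains = n, chromosomes = chroms,
    markers_per_chromosome = mpc, n_subpopulations = subpops, fst = fst,
    sample_missing_rate = miss))
}

parents_for <- function(map) {
  list(a = stats::setNames(rep(0, nrow(map)), map$marker),
       b = stats::setNames(rep(2, nrow(map)), map$marker))
}

small_cross <- function(seed = 3, n_rils = 100, chroms = c(I = 80, II = 80),
                        mpc = 20) {
  panel <- small_panel(seed = seed, n = 4, fst = 0, subpops = 1,
                       chroms = chroms, mpc = mpc)
  par <- parents_for(panel$map)
  g <- simulate_ril_population(par$a, par$b, panel$map, n_rils,
                               selfing_generations = 10, seed = seed + 1)
  list(cross = ril_cross(g, panel$map), map = panel$map, genotypes = g)
}

# Random genotype matrix with dimnames, optionally with missing calls.
random_genotypes <- function(seed, n, m, miss = 0, codes = c(0, 2)) {
  set.seed(seed)
  g <- matrix(sample(codes, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("m%02d", seq_len(m))))
  if (miss > 0) g[runif(n * m) < miss] <- NA
  g
}
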