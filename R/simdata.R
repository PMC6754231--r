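## Synthetic data: structured homozygous isolate panels, biparental RILs,
## and two-trait penetrance phenotypes with replicate-level embryo counts.
## These generators define the statistical structure the downstream scans
## assume, so every analysis stage can be exercised at desk scale.

#' Simulation configuration for a wild-isolate panel
#'
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical output.
#' @param n_strains number of strains (isotypes) to simulate.
#' @param chromosomes named numeric vector of chromosome lengths in cM.
#' @param markers_per_chromosome markers per chromosome (>= 2).
#' @param n_subpopulations number of subpopulations (>= 1).
#' @param fst differentiation between subpopulations in [0, 1); 0 gives a
#'   panmictic panel.
#' @param sample_missing_rate per-call missingness rate in [0, 1).
#' @param genotyping_error_rate per-call probability of flipping a
#'   homozygote to the other homozygote, in [0, 1).
#' @param bp_per_cM physical-to-genetic scaling used to lay markers on a
#'   physical map (default 250 kb/cM, a nematode-like average).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_strains = 100L,
                       chromosomes = c(I = 50, II = 50, III = 50, IV = 50, V = 50, X = 50),
                       markers_per_chromosome = 50L,
                       n_subpopulations = 3L,
                       fst = 0.1,
                       sample_missing_rate = 0,
                       genotyping_error_rate = 0,
                       bp_per_cM = 250000) {
  if (length(chromosomes) < 1 || is.null(names(chromosomes)))
    qg_stop("chromosomes must be a non-empty named vector of cM lengths",
            "qgscan_config_error")
  if (any(chromosomes < 0))
    qg_stop("chromosome lengths must be >= 0", "qgscan_config_error")
  if (markers_per_chromosome < 2)
    qg_stop("need at least 2 markers per chromosome", "qgscan_config_error")
  if (fst < 0 || fst >= 1)
    qg_stop("fst must lie in [0, 1)", "qgscan_config_error")
  if (n_subpopulations < 1)
    qg_stop("n_subpopulations must be >= 1", "qgscan_config_error")
  if (sample_missing_rate < 0 || sample_missing_rate >= 1 ||
      genotyping_error_rate < 0 || genotyping_error_rate >= 1)
    qg_stop("rates must lie in [0, 1)", "qgscan_config_error")
  structure(list(seed = as.integer(seed), n_strains = as.integer(n_strains),
                 chromosomes = chromosomes,
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 n_subpopulations = as.integer(n_subpopulations), fst = fst,
                 sample_missing_rate = sample_missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 bp_per_cM = bp_per_cM),
            class = "sim_config")
}

#' Simulate a structured panel of homozygous wild isolates
#'
#' Emulates a clonal, effectively homozygous isolate collection: marker
#' positions are uniform on each chromosome; each marker has an ancestral
#' allele frequency, and subpopulation frequencies are drawn around it by
#' the Balding-Nichols construction with differentiation \code{fst}
#' (at \code{fst = 0} the subpopulation frequencies equal the ancestral
#' frequency exactly). Strains are homozygous (0 or 2) before optional
#' genotyping-error flips and uniform missingness are injected.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (strains x markers matrix, codes 0/2
#'   plus NA), \code{map} (marker, chrom, bp, cM), and \code{subpop}
#'   (named integer vector of subpopulation labels).
#' @export
simulate_isolate_panel <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  chrs <- config$chromosomes
  mpc <- config$markers_per_chromosome

  maps <- lapply(names(chrs), function(ch) {
    cm <- sort(runif(mpc, 0, chrs[[ch]]))
    data.frame(marker = sprintf("%s_%02d", ch, seq_len(mpc)),
               chrom = ch,
               bp = pmax(1L, as.integer(round(cm * config$bp_per_cM))),
               cM = cm, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  m <- nrow(map)
  n <- config$n_strains
  S <- config$n_subpopulations

  p_anc <- runif(m, 0.05, 0.95)
  if (config$fst > 0 && S > 1) {
    a <- p_anc * (1 - config$fst) / config$fst
    b <- (1 - p_anc) * (1 - config$fst) / config$fst
    p_sub <- matrix(rbeta(S * m, rep(a, each = S), rep(b, each = S)), nrow = S)
  } else {
    p_sub <- matrix(rep(p_anc, each = S), nrow = S)
  }

  subpop <- rep(seq_len(S), length.out = n)
  ## one allele draw per (strain, marker); strains are fully homozygous
  g <- matrix(2L * rbinom(n * m, 1L, p_sub[subpop, , drop = FALSE]), nrow = n)
  if (config$genotyping_error_rate > 0) {
    flip <- runif(n * m) < config$genotyping_error_rate
    g[flip] <- 2L - g[flip]
  }
  if (config$sample_missing_rate > 0)
    g[runif(n * m) < config$sample_missing_rate] <- NA_integer_
  dimnames(g) <- list(sprintf("S%04d", seq_len(n)), map$marker)
  names(subpop) <- rownames(g)
  list(genotypes = g, map = map, subpop = subpop)
}

## Meiosis at marker positions: crossover count ~ Poisson(length in Morgans),
## crossover positions uniform on the chromosome (Haldane, no interference).
## Returns an n x m 0/1 matrix: which parental haplotype the gamete carries
## at each marker.
meiosis_phase <- function(n, pos_cM, length_cM) {
  m <- length(pos_cM)
  k <- rpois(n, length_cM / 100)
  start <- matrix(rbinom(n, 1L, 0.5), nrow = n, ncol = m)
  total <- sum(k)
  if (total == 0L) return(start)
  xo <- runif(total, 0, length_cM)
  id <- rep.int(seq_len(n), k)
  parity <- vapply(pos_cM, function(p) {
    tabulate(id[xo < p], nbins = n) %% 2L
  }, integer(n))
  if (m == 1L) parity <- matrix(parity, ncol = 1L)
  (start + parity) %% 2L
}

#' Simulate a selfed recombinant inbred line population
#'
#' Crosses two fully homozygous parents, selfs the F1 once to produce F2,
#' then selfs for \code{selfing_generations} further rounds (single-seed
#' descent). Meiosis draws a Poisson number of crossovers per chromosome
#' (chromosome length in Morgans) placed uniformly, i.e. the Haldane
#' no-interference model. Output is coded 0 for the parent-A allele,
#' 2 for parent B, and 1 for residual heterozygotes, which decay as
#' (1/2)^(selfing_generations + 1) per locus.
#'
#' @param parent_a,parent_b parental genotype vectors, homozygous (0 or 2)
#'   and distinct at every marker; names must match \code{map$marker} if set.
#' @param map marker map (marker, chrom, bp, cM), sorted within chromosome.
#' @param n_rils number of lines to simulate.
#' @param selfing_generations selfing rounds after the F2 (10 in a typical
#'   RIL panel).
#' @param seed integer seed.
#' @return strains x markers matrix coded 0/1/2.
#' @export
simulate_ril_population <- function(parent_a, parent_b, map, n_rils,
                                    selfing_generations = 10L, seed = 1L) {
  check_marker_map(map)
  m <- nrow(map)
  if (length(parent_a) != m || length(parent_b) != m)
    qg_stop("parent haplotypes must cover every marker in the map",
            "qgscan_precondition_error")
  if (any(is.na(parent_a)) || any(is.na(parent_b)) ||
      !all(parent_a %in% c(0, 2)) || !all(parent_b %in% c(0, 2)))
    qg_stop("parents must be fully homozygous (codes 0/2, no missing)",
            "qgscan_precondition_error")
  if (any(parent_a == parent_b))
    qg_stop("parents must be distinct at every marker",
            "qgscan_precondition_error")
  if (selfing_generations < 0)
    qg_stop("selfing_generations must be >= 0", "qgscan_precondition_error")
  set.seed(seed)

  n <- as.integer(n_rils)
  ## haplotypes as 0 (parent A allele) / 1 (parent B allele)
  h1 <- matrix(0L, n, m)
  h2 <- matrix(1L, n, m)
  chrom_idx <- split(seq_len(m), factor(map$chrom, levels = unique(map$chrom)))
  n_selfings <- 1L + as.integer(selfing_generations)
  for (gen in seq_len(n_selfings)) {
    new1 <- h1; new2 <- h2
    for (ci in chrom_idx) {
      pos <- map$cM[ci]
      len <- max(pos)
      ph1 <- meiosis_phase(n, pos, len)
      ph2 <- meiosis_phase(n, pos, len)
      a <- h1[, ci, drop = FALSE]; b <- h2[, ci, drop = FALSE]
      new1[, ci] <- ifelse(ph1 == 0L, a, b)
      new2[, ci] <- ifelse(ph2 == 0L, a, b)
    }
    h1 <- new1; h2 <- new2
  }
  g <- h1 + h2   # 0 = A/A, 1 = het, 2 = B/B
  dimnames(g) <- list(sprintf("RIL%04d", seq_len(n)), map$marker)
  g
}

#' Trait architecture for penetrance phenotype simulation
#'
#' @param baseline named numeric vector of baseline liabilities, one per
#'   trait (logit scale; 0 corresponds to 50\% penetrance).
#' @param qtls data frame with columns chrom, pos_cM, and one effect column
#'   per trait (effect_trait1, effect_trait2, ...). An effect is the
#'   liability-scale contrast between the two homozygous classes.
#' @param polygenic_n_loci,polygenic_sd number of background loci and the
#'   total liability SD they contribute across strains.
#' @param strain_sd liability-scale SD of strain-level noise beyond binomial
#'   sampling (captures micro-environmental reproducibility limits).
#' @param embryos_per_replicate embryos scored per replicate (default 500,
#'   a typical scoring depth per strain and replicate).
#' @param replicates replicates per strain (default 2).
#' @return a list of class \code{trait_architecture}.
#' @export
trait_architecture <- function(baseline = c(trait1 = 0, trait2 = 0),
                               qtls = NULL,
                               polygenic_n_loci = 0L,
                               polygenic_sd = 0,
                               strain_sd = 0.2,
                               embryos_per_replicate = 500L,
                               replicates = 2L) {
  if (embryos_per_replicate < 1 || replicates < 1)
    qg_stop("embryos_per_replicate and replicates must be >= 1",
            "qgscan_config_error")
  if (polygenic_sd < 0 || strain_sd < 0)
    qg_stop("SD parameters must be >= 0", "qgscan_config_error")
  if (is.null(qtls))
    qtls <- data.frame(chrom = character(), pos_cM = numeric())
  structure(list(baseline = baseline, qtls = qtls,
                 polygenic_n_loci = as.integer(polygenic_n_loci),
                 polygenic_sd = polygenic_sd, strain_sd = strain_sd,
                 embryos_per_replicate = as.integer(embryos_per_replicate),
                 replicates = as.integer(replicates)),
            class = "trait_architecture")
}

#' Simulate penetrance phenotypes on a genotyped panel
#'
#' Per strain and trait, a liability is assembled as baseline + QTL dosage
#' effects + polygenic background + strain noise, mapped to a penetrance
#' through the logistic link (clipped to [1e-6, 1 - 1e-6]), and observed as
#' replicate-level binomial counts of embryos with differentiated gut.
#' QTL positions are resolved to the nearest marker on their chromosome;
#' dosage is the alternate-allele fraction (0, 1/2, 1), so a QTL effect is
#' the full homozygote-vs-homozygote liability contrast. The polygenic
#' background is realized through many small-effect marker loci, so
#' kinship confounding is genotype-borne and visible to a mixed model.
#'
#' @param genotypes strains x markers matrix coded 0/1/2 (NA allowed;
#'   missing dosages are mean-imputed for liability assembly only).
#' @param map marker map matching the genotype columns.
#' @param arch a \code{\link{trait_architecture}}.
#' @param kinship_like_background logical; include the polygenic term.
#' @param seed integer seed.
#' @return long-format data frame: strain, trait, value, n_scored,
#'   n_with_gut, replicate; \code{value = n_with_gut / n_scored}.
#' @export
simulate_phenotypes <- function(genotypes, map, arch,
                                kinship_like_background = TRUE, seed = 1L) {
  check_genotypes(genotypes)
  check_marker_map(map, colnames(genotypes))
  if (!inherits(arch, "trait_architecture"))
    qg_stop("arch must be a trait_architecture", "qgscan_config_error")
  set.seed(seed)

  n <- nrow(genotypes)
  traits <- names(arch$baseline)
  dose <- genotypes / 2
  if (anyNA(dose)) {
    mu <- colMeans(dose, na.rm = TRUE)
    idx <- which(is.na(dose), arr.ind = TRUE)
    dose[idx] <- mu[idx[, 2]]
  }

  liab <- matrix(rep(arch$baseline, each = n), nrow = n,
                 dimnames = list(rownames(genotypes), traits))
  if (nrow(arch$qtls)) {
    for (k in seq_len(nrow(arch$qtls))) {
      q <- arch$qtls[k, ]
      on_chr <- which(map$chrom == q$chrom)
      if (!length(on_chr))
        qg_stop(sprintf("QTL on unknown chromosome '%s'", q$chrom),
                "qgscan_config_error")
      j <- on_chr[which.min(abs(map$cM[on_chr] - q$pos_cM))]
      for (tr in traits) {
        eff_col <- paste0("effect_", tr)
        if (!is.null(arch$qtls[[eff_col]]))
          liab[, tr] <- liab[, tr] + dose[, j] * arch$qtls[[eff_col]][k]
      }
    }
  }
  if (kinship_like_background && arch$polygenic_n_loci > 0 && arch$polygenic_sd > 0) {
    loci <- sample.int(ncol(dose), min(arch$polygenic_n_loci, ncol(dose)))
    for (tr in traits) {
      b <- rnorm(length(loci))
      score <- as.numeric(scale(dose[, loci, drop = FALSE] %*% b))
      score[is.na(score)] <- 0
      liab[, tr] <- liab[, tr] + score * arch$polygenic_sd
    }
  }
  if (arch$strain_sd > 0)
    liab <- liab + matrix(rnorm(n * length(traits), 0, arch$strain_sd), n)

  pen <- pmin(pmax(plogis(liab), 1e-6), 1 - 1e-6)
  out <- expand.grid(replicate = seq_len(arch$replicates),
                     strain = rownames(genotypes), trait = traits,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p_row <- pen[cbind(out$strain, out$trait)]
  out$n_scored <- arch$embryos_per_replicate
  out$n_with_gut <- rbinom(nrow(out), out$n_scored, p_row)
  out$value <- out$n_with_gut / out$n_scored
  out[, c("strain", "trait", "value", "n_scored", "n_with_gut", "replicate")]
}

#' Simulate a continuous trait on a phylogeny under Pagel's lambda
#'
#' Draws tip values from a multivariate normal whose covariance is the
#' Brownian-motion shared-path-length matrix with off-diagonal entries
#' scaled by \code{lambda} and diagonal unchanged, times \code{rate}.
#' \code{lambda = 0} gives independent tips; \code{lambda = 1} is plain
#' Brownian motion.
#'
#' @param tree an \code{ape::phylo} with positive branch lengths.
#' @param lambda_true signal strength in [0, 1].
#' @param rate Brownian rate (variance per unit branch length), > 0.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_trait_on_tree <- function(tree, lambda_true, rate = 1, seed = 1L) {
  if (lambda_true < 0 || lambda_true > 1)
    qg_stop("lambda must lie in [0, 1]", "qgscan_domain_error")
  if (rate <= 0)
    qg_stop("rate must be > 0", "qgscan_domain_error")
  if (any(tree$edge.length < 0))
    qg_stop("tree must have nonnegative branch lengths", "qgscan_precondition_error")
  set.seed(seed)
  C <- ape::vcv(tree)
  Cl <- lambda_true * C
  diag(Cl) <- diag(C)
  L <- chol(rate * Cl + diag(1e-12, nrow(C)))
  setNames(as.numeric(crossprod(L, rnorm(nrow(C)))), rownames(C))
}
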