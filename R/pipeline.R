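## Orchestration: a single configuration drives simulate -> gwas -> qtl ->
## phylo -> reciprocity and collects a machine-readable report. Every
## stochastic stage draws its seed deterministically from the global seed
## and the stage name, so stage results are reproducible regardless of
## which other stages are enabled.

#' Pipeline configuration
#'
#' @param seed global seed; per-stage substreams are derived from it.
#' @param stages character vector of stages to run, in dependency order,
#'   from: simulate, gwas, qtl, phylo, reciprocity.
#' @param out_dir optional directory; when set, stage artifacts are written
#'   there in the documented text formats (012 trio, phenotype CSV, map
#'   TSV, Newick, JSON report).
#' @param panel arguments for \code{\link{sim_config}} (the isolate panel).
#' @param ril list: n_rils, selfing_generations.
#' @param arch arguments for \code{\link{trait_architecture}} shared by the
#'   panel and RIL phenotypes.
#' @param gwas list: min_maf, n_permutations, alpha.
#' @param qtl list: step_cM, error_rate, n_permutations, alpha, drop.
#' @param phylo list: trait (which trait to test for signal).
#' @param reciprocity list: window_size, step, r2_threshold, zscore_cutoff,
#'   min_class_size.
#' @return list of class \code{run_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "gwas", "qtl", "phylo",
                                       "reciprocity"),
                            out_dir = NULL,
                            panel = list(),
                            ril = list(n_rils = 95L, selfing_generations = 10L),
                            arch = list(),
                            gwas = list(min_maf = 0.05, n_permutations = 200L,
                                        alpha = 0.05),
                            qtl = list(step_cM = 1, error_rate = 1e-4,
                                       n_permutations = 200L, alpha = 0.05,
                                       drop = 1.5),
                            phylo = list(trait = "trait1"),
                            reciprocity = list(window_size = 50L, step = 5L,
                                               r2_threshold = 0.8,
                                               zscore_cutoff = 1.96,
                                               min_class_size = 3L)) {
  known <- c("simulate", "gwas", "qtl", "phylo", "reciprocity")
  if (!all(stages %in% known))
    qg_stop(sprintf("unknown stage(s): %s",
                    paste(setdiff(stages, known), collapse = ", ")),
            "qgscan_config_error")
  structure(list(seed = as.integer(seed), stages = stages, out_dir = out_dir,
                 panel = panel, ril = ril, arch = arch, gwas = gwas,
                 qtl = qtl, phylo = phylo, reciprocity = reciprocity),
            class = "run_config")
}

#' Run the synthetic end-to-end benchmark
#'
#' Executes the enabled stages in dependency order. The simulate stage
#' builds an isolate panel, an N2xMY16-like RIL population on the same
#' map, and two-trait penetrance phenotypes for both; downstream stages
#' consume those objects. A failure in one stage aborts its dependents
#' with a clear diagnostic. Re-running an identical configuration
#' reproduces identical stochastic summaries.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{run_report}: per-stage parameter echoes and
#'   headline statistics, plus the simulated/derived objects under
#'   \code{$objects}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "run_config"))
    qg_stop("config must come from pipeline_config()", "qgscan_config_error")
  stages <- config$stages
  report <- list(seed = config$seed, stages = stages)
  obj <- list()

  if ("simulate" %in% stages) {
    pargs <- config$panel
    pargs$seed <- substream_seed(config$seed, "simulate_panel")
    panel <- simulate_isolate_panel(do.call(sim_config, pargs))
    arch <- do.call(trait_architecture, config$arch)
    panel_pheno <- simulate_phenotypes(
      panel$genotypes, panel$map, arch,
      seed = substream_seed(config$seed, "simulate_panel_pheno"))
    parent_a <- setNames(rep(0, nrow(panel$map)), panel$map$marker)
    parent_b <- setNames(rep(2, nrow(panel$map)), panel$map$marker)
    rils <- simulate_ril_population(
      parent_a, parent_b, panel$map,
      n_rils = config$ril$n_rils,
      selfing_generations = config$ril$selfing_generations,
      seed = substream_seed(config$seed, "simulate_ril"))
    ril_pheno <- simulate_phenotypes(
      rils, panel$map, arch,
      seed = substream_seed(config$seed, "simulate_ril_pheno"))
    obj <- list(panel = panel, panel_pheno = panel_pheno, rils = rils,
                ril_pheno = ril_pheno, map = panel$map, arch = arch)
    report$simulate <- list(
      n_strains = nrow(panel$genotypes), n_markers = ncol(panel$genotypes),
      n_rils = nrow(rils),
      panel_digest = round(mean(panel$genotypes, na.rm = TRUE), 10),
      ril_het_fraction = round(mean(rils == 1), 10))
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_012_trio(panel$genotypes, panel$map,
                     file.path(config$out_dir, "panel"))
      write_012_trio(rils, panel$map, file.path(config$out_dir, "rils"))
      write_marker_map(panel$map, file.path(config$out_dir, "map.tsv"))
      write_phenotypes(panel_pheno,
                       file.path(config$out_dir, "panel_phenotypes.csv"))
      write_phenotypes(ril_pheno,
                       file.path(config$out_dir, "ril_phenotypes.csv"))
    }
  }

  need <- function(what, stage) {
    if (is.null(obj[[what]]))
      qg_stop(sprintf("stage '%s' needs '%s' from the simulate stage", stage,
                      what), "qgscan_config_error")
    obj[[what]]
  }

  if ("gwas" %in% stages) {
    panel <- need("panel", "gwas")
    y <- trait_vector(obj$panel_pheno, "trait1")
    K <- ibs_kinship(panel$genotypes)
    scan <- emma_scan(y, panel$genotypes, K, min_maf = config$gwas$min_maf,
                      map = panel$map)
    fdr <- permutation_fdr(scan, y, panel$genotypes, K,
                           n_permutations = config$gwas$n_permutations,
                           seed = substream_seed(config$seed, "gwas_perm"),
                           alpha = config$gwas$alpha)
    obj$gwas <- list(scan = scan, fdr = fdr)
    top <- scan[scan$tested, ]
    top <- top[which.min(top$p), ]
    report$gwas <- list(
      n_tested = sum(scan$tested),
      top_marker = top$marker, top_minus_log10_p = round(top$minus_log10_p, 6),
      n_fdr_05 = sum(fdr$table$fdr <= 0.05),
      gw_threshold_minus_log10_p = round(fdr$gw_threshold_minus_log10_p, 6),
      params = config$gwas)
  }

  if ("qtl" %in% stages) {
    rils <- need("rils", "qtl")
    map <- obj$map
    cross <- ril_cross(rils, map)
    qp <- config$qtl
    gp <- calc_genoprob(cross, qp$step_cM, qp$error_rate)
    scans <- lapply(c("trait1", "trait2"), function(tr) {
      y <- trait_vector(obj$ril_pheno, tr)
      curve <- scanone_em(cross, y, genoprob = gp)
      thr <- permutation_threshold(
        cross, y, n_permutations = qp$n_permutations, alpha = qp$alpha,
        seed = substream_seed(config$seed, paste0("qtl_perm_", tr)),
        genoprob = gp)
      peaks <- lapply(unique(map$chrom), function(ch)
        lod_support_interval(curve, ch, qp$drop))
      sig <- Filter(function(p) p$found && p$peak_lod >= thr$threshold, peaks)
      list(trait = tr, curve = curve, threshold = thr, peaks = sig)
    })
    names(scans) <- c("trait1", "trait2")
    obj$qtl <- scans
    report$qtl <- lapply(scans, function(s) list(
      max_lod = round(max(s$curve$lod), 6),
      threshold = round(s$threshold$threshold, 6),
      significant_chroms = vapply(s$peaks, `[[`, "", "chrom")))
    report$qtl$params <- config$qtl
  }

  if ("phylo" %in% stages) {
    panel <- need("panel", "phylo")
    D <- snp_distance(panel$genotypes)
    tree <- neighbor_joining(D)
    y <- trait_vector(obj$panel_pheno, config$phylo$trait)
    fit <- pagel_lambda(tree, y)
    obj$phylo <- list(tree = tree, fit = fit)
    report$phylo <- list(lambda = round(fit$lambda, 6), p = round(fit$p, 6),
                         trait = config$phylo$trait)
    if (!is.null(config$out_dir))
      write_newick(tree, file.path(config$out_dir, "panel_nj.nwk"))
  }

  if ("reciprocity" %in% stages) {
    rils <- need("rils", "reciprocity")
    rp <- config$reciprocity
    y1 <- trait_vector(obj$ril_pheno, "trait1")
    y2 <- trait_vector(obj$ril_pheno, "trait2")
    tab <- per_snp_allelic_effect(rils, y1, y2,
                                  min_class_size = rp$min_class_size,
                                  map = obj$map)
    keep <- ld_prune(rils, rp$window_size, rp$step, rp$r2_threshold,
                     map = obj$map)
    tab <- apply_prune(tab, keep)
    tab <- zscore_outlier_filter(tab, rp$zscore_cutoff)
    rep_r <- cross_trait_correlation(tab)
    sl <- strain_level_correlation(y1, y2)
    obj$reciprocity <- list(table = tab, report = rep_r, strain_level = sl)
    report$reciprocity <- list(
      genome_R = round(rep_r$genome$R, 6), genome_p = round(rep_r$genome$p, 6),
      n_markers = rep_r$genome$n,
      strain_rho = round(sl$rho, 6), strain_p = round(sl$p, 6),
      stage_counts = as.list(rep_r$stage_counts), params = rp)
  }

  if (!is.null(config$out_dir)) {
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(c(report, list(objects = obj)), class = "run_report")
}

#' Standard phenotype-group comparisons for reporting
#'
#' Delegates to the standard routines: a two-sided Fisher exact test for a
#' 2x2 count table (e.g. embryos with/without gut in two strains) and a
#' two-sided Welch t-test for per-group replicate values.
#'
#' @param counts optional 2x2 matrix of nonnegative counts.
#' @param group1,group2 optional numeric vectors of replicate values.
#' @return data.frame with one row per performed test: test, statistic,
#'   p.
#' @export
compare_phenotype_groups <- function(counts = NULL, group1 = NULL,
                                     group2 = NULL) {
  rows <- list()
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == c(2, 2)) || any(counts < 0))
      qg_stop("counts must be a nonnegative 2x2 table", "qgscan_precondition_error")
    ft <- fisher.test(counts)
    rows <- c(rows, list(data.frame(test = "fisher_exact",
                                    statistic = unname(ft$estimate),
                                    p = ft$p.value)))
  }
  if (!is.null(group1) && !is.null(group2)) {
    if (sd(group1) == 0 && sd(group2) == 0 &&
        mean(group1) == mean(group2)) {
      rows <- c(rows, list(data.frame(test = "welch_t", statistic = 0, p = 1)))
    } else {
      tt <- t.test(group1, group2)
      rows <- c(rows, list(data.frame(test = "welch_t",
                                      statistic = unname(tt$statistic),
                                      p = tt$p.value)))
    }
  }
  if (!length(rows))
    qg_stop("provide counts and/or two groups", "qgscan_config_error")
  do.call(rbind, rows)
}
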