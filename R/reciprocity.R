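## Cross-trait reciprocal allelic-effect analysis: per-SNP differences of
## median phenotypes between the two allele classes for two traits,
## LD pruning, single-pass z-score outlier removal, and genome-wide /
## per-chromosome Pearson correlation of the paired effects. The fixed
## pipeline order is: class-size filter -> LD prune -> effect computation
## -> outlier filter -> correlate.

#' Per-SNP allelic effects for two traits
#'
#' For every marker, the allelic effect on a trait is
#' median(phenotype | alternate-allele homozygotes) - median(phenotype |
#' reference homozygotes). The reference class is the reference /
#' parent-A allele (code 0) for both traits, so effect signs are
#' comparable across traits. Heterozygote and missing calls are excluded
#' from the classes. Markers where either class has fewer than
#' \code{min_class_size} strains are excluded with a reason, not an error.
#'
#' @param genotypes strains x markers matrix coded 0/1/2/NA.
#' @param pheno1,pheno2 named phenotype vectors (the strain sets are
#'   intersected with the genotyped strains; a message reports the count).
#' @param min_class_size minimum strains per homozygote class (default 3).
#' @param map optional marker map for chrom/bp annotation.
#' @return data.frame of class \code{allelic_effect_table}: marker, chrom,
#'   bp, n_ref, n_alt, effect_trait1, effect_trait2, included, reason.
#' @export
per_snp_allelic_effect <- function(genotypes, pheno1, pheno2,
                                   min_class_size = 3, map = NULL) {
  check_genotypes(genotypes)
  strains <- Reduce(intersect, list(rownames(genotypes),
                                    names(pheno1)[!is.na(pheno1)],
                                    names(pheno2)[!is.na(pheno2)]))
  if (length(strains) < 2 * min_class_size)
    qg_stop("too few strains shared between traits and genotypes",
            "qgscan_data_error")
  if (length(strains) < nrow(genotypes))
    message(sprintf("per_snp_allelic_effect: using %d of %d strains shared by both traits",
                    length(strains), nrow(genotypes)))
  g <- genotypes[strains, , drop = FALSE]
  y1 <- pheno1[strains]; y2 <- pheno2[strains]

  m <- ncol(g)
  out <- data.frame(marker = colnames(g),
                    chrom = NA_character_, bp = NA_integer_,
                    n_ref = 0L, n_alt = 0L,
                    effect_trait1 = NA_real_, effect_trait2 = NA_real_,
                    included = FALSE, reason = "", stringsAsFactors = FALSE)
  if (!is.null(map)) {
    check_marker_map(map, colnames(g))
    out$chrom <- map$chrom
    out$bp <- map$bp
  }
  for (j in seq_len(m)) {
    ref <- which(!is.na(g[, j]) & g[, j] == 0)
    alt <- which(!is.na(g[, j]) & g[, j] == 2)
    out$n_ref[j] <- length(ref); out$n_alt[j] <- length(alt)
    if (length(ref) < min_class_size || length(alt) < min_class_size) {
      out$reason[j] <- "class_size"
      next
    }
    out$effect_trait1[j] <- median(y1[alt]) - median(y1[ref])
    out$effect_trait2[j] <- median(y2[alt]) - median(y2[ref])
    out$included[j] <- TRUE
  }
  attr(out, "n_strains") <- length(strains)
  attr(out, "min_class_size") <- min_class_size
  class(out) <- c("allelic_effect_table", "data.frame")
  out
}

#' Sliding-window LD pruning (indep-pairwise style)
#'
#' Greedy pruning over map-ordered markers: within each window of
#' \code{window_size} markers (windows never span chromosomes when a map
#' is supplied), while any retained pair has squared genotype correlation
#' above \code{r2_threshold}, the pair with the highest r-squared is
#' resolved by removing its lower-MAF member (ties: the later map
#' position); the window then advances by \code{step} markers.
#'
#' @param genotypes strains x markers matrix, markers in map order.
#' @param window_size window width in markers (>= 2).
#' @param step window advance in markers.
#' @param r2_threshold squared-correlation threshold above which a pair is
#'   pruned.
#' @param map optional marker map; restricts windows to chromosomes.
#' @return character vector of retained marker names, with the removed
#'   markers as attribute \code{removed}.
#' @export
ld_prune <- function(genotypes, window_size = 50, step = 5,
                     r2_threshold = 0.8, map = NULL) {
  check_genotypes(genotypes)
  if (window_size < 2)
    qg_stop("window_size must be >= 2", "qgscan_config_error")
  if (step < 1)
    qg_stop("step must be >= 1", "qgscan_config_error")
  markers <- colnames(genotypes)
  chrom <- if (!is.null(map)) {
    check_marker_map(map, markers)
    map$chrom
  } else rep("all", length(markers))
  maf <- marker_maf(genotypes)
  removed <- logical(length(markers))

  for (ch in unique(chrom)) {
    cidx <- which(chrom == ch)
    start <- 1L
    repeat {
      win <- cidx[seq(start, min(start + window_size - 1L, length(cidx)))]
      live <- win[!removed[win]]
      while (length(live) >= 2) {
        cm <- suppressWarnings(
          cor(genotypes[, live, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        cm[!is.finite(cm)] <- 0
        diag(cm) <- 0
        if (max(cm) <= r2_threshold) break
        pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
        a <- live[pair[1]]; b <- live[pair[2]]
        drop <- if (isTRUE(maf[a] < maf[b])) a
                else if (isTRUE(maf[b] < maf[a])) b
                else max(a, b)           # tie: later map position
        removed[drop] <- TRUE
        live <- win[!removed[win]]
      }
      if (start + window_size - 1L >= length(cidx)) break
      start <- start + step
    }
  }
  out <- markers[!removed]
  attr(out, "removed") <- markers[removed]
  out
}

#' Single-pass z-score outlier filter on allelic effects
#'
#' Computes, per trait, z-scores of the included effects from that trait's
#' mean and sample standard deviation, and excludes markers with |z| >
#' \code{cutoff} in either trait. The statistics are not recomputed after
#' removals: the contract is a single pass (applying the filter again to
#' its own output, with recomputed statistics, may remove more).
#'
#' @param table an \code{\link{per_snp_allelic_effect}} result.
#' @param cutoff z-score cutoff (default 1.96, the central 95\% of a
#'   normal distribution).
#' @return the table with outliers marked excluded (reason "outlier").
#' @export
zscore_outlier_filter <- function(table, cutoff = 1.96) {
  inc <- which(table$included)
  if (length(inc) < 3)
    qg_stop("need at least 3 included markers", "qgscan_precondition_error")
  drop <- rep(FALSE, length(inc))
  for (col in c("effect_trait1", "effect_trait2")) {
    x <- table[[col]][inc]
    s <- sd(x)
    if (s == 0) {
      warning(sprintf("%s has zero variance: no outliers removed", col))
      next
    }
    drop <- drop | abs((x - mean(x)) / s) > cutoff
  }
  table$included[inc[drop]] <- FALSE
  table$reason[inc[drop]] <- "outlier"
  attr(table, "zscore_cutoff") <- cutoff
  table
}

#' Mark markers removed by LD pruning in an effect table
#'
#' @param table an \code{\link{per_snp_allelic_effect}} result.
#' @param retained character vector from \code{\link{ld_prune}}.
#' @return the table with non-retained markers excluded (reason "pruned").
#' @export
apply_prune <- function(table, retained) {
  pruned <- table$included & !(table$marker %in% retained)
  table$included[pruned] <- FALSE
  table$reason[pruned] <- "pruned"
  table
}

#' Genome-wide and per-chromosome correlation of allelic effects
#'
#' Pearson correlation between the two traits' allelic effects over
#' included markers, genome-wide and per chromosome; p-values from the t
#' transform with df = m - 2. Groups with fewer than 3 markers are
#' reported as undefined (NA), not an error.
#'
#' @param table an \code{\link{per_snp_allelic_effect}} result (after any
#'   pruning/outlier filtering).
#' @return list of class \code{reciprocity_report}: \code{genome} (R, p,
#'   n), \code{by_chrom} data.frame, \code{stage_counts}, \code{config}.
#' @export
cross_trait_correlation <- function(table) {
  inc <- table[table$included, , drop = FALSE]
  if (nrow(inc) < 3)
    qg_stop("fewer than 3 markers included after filtering", "qgscan_data_error")
  pearson <- function(x, y) {
    m <- length(x)
    if (m < 3 || sd(x) == 0 || sd(y) == 0)
      return(c(R = NA_real_, p = NA_real_, n = m))
    r <- cor(x, y)
    tt <- r * sqrt((m - 2) / max(1 - r^2, .Machine$double.eps))
    c(R = r, p = 2 * pt(-abs(tt), m - 2), n = m)
  }
  genome <- pearson(inc$effect_trait1, inc$effect_trait2)
  chroms <- unique(table$chrom[!is.na(table$chrom)])
  by_chrom <- do.call(rbind, lapply(chroms, function(ch) {
    sub <- inc[!is.na(inc$chrom) & inc$chrom == ch, ]
    v <- pearson(sub$effect_trait1, sub$effect_trait2)
    data.frame(chrom = ch, R = v[["R"]], p = v[["p"]], n = v[["n"]],
               undefined = v[["n"]] < 3)
  }))
  counts <- c(raw = nrow(table),
              class_size_pass = sum(table$reason != "class_size"),
              after_prune = sum(table$reason %in% c("", "outlier")),
              included = nrow(inc))
  structure(list(genome = as.list(genome), by_chrom = by_chrom,
                 stage_counts = counts,
                 config = list(min_class_size = attr(table, "min_class_size"),
                               zscore_cutoff = attr(table, "zscore_cutoff"))),
            class = "reciprocity_report")
}

#' Strain-level correlation between two penetrance traits
#'
#' Spearman rank correlation with average ranks for ties; the p-value uses
#' the t approximation t = rho sqrt((n - 2) / (1 - rho^2)).
#'
#' @param pheno1,pheno2 named phenotype vectors; strains are intersected.
#' @return list: \code{rho}, \code{p}, \code{n}.
#' @export
strain_level_correlation <- function(pheno1, pheno2) {
  shared <- intersect(names(pheno1)[!is.na(pheno1)],
                      names(pheno2)[!is.na(pheno2)])
  n <- length(shared)
  if (n < 4)
    qg_stop("need at least 4 paired strains", "qgscan_sample_size_error")
  r1 <- rank(pheno1[shared]); r2 <- rank(pheno2[shared])
  rho <- cor(r1, r2)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tt), n - 2)
  list(rho = rho, p = p, n = n)
}

#' @exportS3Method base::print
print.reciprocity_report <- function(x, ...) {
  cat(sprintf("Cross-trait allelic-effect correlation (%d markers included)\n",
              x$genome$n))
  cat(sprintf("  genome-wide Pearson R = %.4f, p = %.4g\n",
              x$genome$R, x$genome$p))
  if (!is.null(x$by_chrom) && nrow(x$by_chrom)) {
    for (i in seq_len(nrow(x$by_chrom)))
      cat(sprintf("  %-6s R = %6s  (n = %d)\n", x$by_chrom$chrom[i],
                  ifelse(x$by_chrom$undefined[i], "NA",
                         sprintf("%.3f", x$by_chrom$R[i])),
                  x$by_chrom$n[i]))
  }
  cat("  filter chain: ", paste(names(x$stage_counts), x$stage_counts,
                                sep = "=", collapse = " -> "), "\n")
  invisible(x)
}
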