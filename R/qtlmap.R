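## Interval mapping for selfed recombinant inbred lines: a two-state
## hidden Markov model along each chromosome (states = the two parental
## homozygotes; residual heterozygotes are treated as missing
## observations), an EM likelihood scan on the marker + pseudomarker grid,
## permutation-based genome-wide thresholds, and 1.5-LOD support intervals.

#' Haldane inverse map function
#'
#' Converts a genetic distance in cM to a recombination fraction under the
#' no-interference (Haldane) model: r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d distance in cM, >= 0.
#' @return recombination fraction in [0, 0.5).
#' @export
map_to_recfrac <- function(d) {
  if (any(d < 0)) qg_stop("distance must be >= 0", "qgscan_domain_error")
  (1 - exp(-2 * d / 100)) / 2
}

#' Haldane-Waddington correction for selfed RILs
#'
#' Repeated selfing expands the map: the chance that two loci with
#' per-meiosis recombination fraction r end up with discordant parental
#' genotypes in a fully inbred selfed line is R = 2 r / (1 + 2 r).
#'
#' @param r per-meiosis recombination fraction in [0, 0.5].
#' @return RIL-level recombinant fraction.
#' @export
ril_recfrac <- function(r) {
  if (any(r < 0 | r > 0.5))
    qg_stop("recombination fraction must lie in [0, 0.5]", "qgscan_domain_error")
  2 * r / (1 + 2 * r)
}

#' Construct a selfed-RIL cross object
#'
#' @param genotypes RILs x markers matrix coded 0 (parent A), 1 (residual
#'   heterozygote), 2 (parent B), NA missing.
#' @param map marker map with cM positions, sorted within chromosome.
#' @return list of class \code{ril_cross}.
#' @export
ril_cross <- function(genotypes, map) {
  check_genotypes(genotypes)
  check_marker_map(map, colnames(genotypes))
  if (anyNA(map$cM))
    qg_stop("cross map needs genetic (cM) positions; see assign_cM_from_bp()",
            "qgscan_precondition_error")
  for (ch in unique(map$chrom))
    if (is.unsorted(map$cM[map$chrom == ch]))
      qg_stop(sprintf("map not sorted on chromosome %s", ch),
              "qgscan_precondition_error")
  structure(list(genotypes = genotypes, map = map), class = "ril_cross")
}

## Evaluation grid: markers plus pseudomarkers every step cM.
.eval_grid <- function(map, step_cM) {
  grids <- lapply(unique(map$chrom), function(ch) {
    sub <- map[map$chrom == ch, ]
    pos <- sub$cM
    ids <- as.character(sub$marker)
    if (step_cM > 0 && max(pos) > min(pos)) {
      ps <- seq(min(pos), max(pos), by = step_cM)
      keep <- vapply(ps, function(p) min(abs(p - pos)) > 1e-8, logical(1))
      ps <- ps[keep]
      pos <- c(pos, ps)
      ids <- c(ids, sprintf("c%s.loc%g", ch, ps))
      o <- order(pos)
      pos <- pos[o]; ids <- ids[o]
    }
    data.frame(chrom = ch, pos_cM = pos, id = ids,
               is_marker = ids %in% sub$marker, stringsAsFactors = FALSE)
  })
  do.call(rbind, grids)
}

#' Genotype probabilities along the RIL genome
#'
#' Forward-backward smoothing of a two-state Markov chain per chromosome:
#' transition probability between consecutive evaluation positions is the
#' RIL-corrected Haldane recombination fraction for their cM separation,
#' and emissions allow a genotyping error rate (an observed homozygote is
#' the true state with probability 1 - error_rate). Heterozygote calls are
#' treated as missing observations, the selfed-RIL two-class convention.
#'
#' @param cross a \code{\link{ril_cross}}.
#' @param step_cM pseudomarker spacing in cM (default 1; 0 = markers only).
#' @param error_rate genotyping error rate (default 1e-4).
#' @return list of class \code{genoprob}: \code{grid} (chrom, pos_cM, id,
#'   is_marker) and \code{prob}, an RILs x positions matrix of P(parent-B
#'   homozygote); P(parent A) is its complement.
#' @export
calc_genoprob <- function(cross, step_cM = 1, error_rate = 1e-4) {
  if (!inherits(cross, "ril_cross")) qg_stop("need a ril_cross", "qgscan_precondition_error")
  if (step_cM < 0) qg_stop("step_cM must be >= 0", "qgscan_precondition_error")
  g <- cross$genotypes
  map <- cross$map
  n <- nrow(g)
  grid <- .eval_grid(map, step_cM)
  prob <- matrix(NA_real_, n, nrow(grid),
                 dimnames = list(rownames(g), grid$id))
  e <- error_rate

  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    pos <- grid$pos_cM[gi]
    np <- length(gi)
    ## emission matrices per position: columns (state A, state B)
    emitA <- matrix(1, n, np)
    emitB <- matrix(1, n, np)
    mk <- which(grid$is_marker[gi])
    obs <- g[, match(grid$id[gi][mk], colnames(g)), drop = FALSE]
    oA <- !is.na(obs) & obs == 0
    oB <- !is.na(obs) & obs == 2
    emitA[, mk][oA] <- 1 - e; emitB[, mk][oA] <- e
    emitA[, mk][oB] <- e;     emitB[, mk][oB] <- 1 - e
    r <- ril_recfrac(map_to_recfrac(diff(pos)))

    fA <- matrix(0, n, np); fB <- matrix(0, n, np)
    fA[, 1] <- 0.5 * emitA[, 1]; fB[, 1] <- 0.5 * emitB[, 1]
    sc <- fA[, 1] + fB[, 1]
    fA[, 1] <- fA[, 1] / sc; fB[, 1] <- fB[, 1] / sc
    for (t in seq_len(np - 1)) {
      aA <- fA[, t] * (1 - r[t]) + fB[, t] * r[t]
      aB <- fA[, t] * r[t] + fB[, t] * (1 - r[t])
      fA[, t + 1] <- aA * emitA[, t + 1]
      fB[, t + 1] <- aB * emitB[, t + 1]
      sc <- fA[, t + 1] + fB[, t + 1]
      fA[, t + 1] <- fA[, t + 1] / sc; fB[, t + 1] <- fB[, t + 1] / sc
    }
    bA <- matrix(1, n, np); bB <- matrix(1, n, np)
    for (t in rev(seq_len(np - 1))) {
      nbA <- bA[, t + 1] * emitA[, t + 1]
      nbB <- bB[, t + 1] * emitB[, t + 1]
      bA[, t] <- (1 - r[t]) * nbA + r[t] * nbB
      bB[, t] <- r[t] * nbA + (1 - r[t]) * nbB
      sc <- bA[, t] + bB[, t]
      bA[, t] <- bA[, t] / sc; bB[, t] <- bB[, t] / sc
    }
    pB <- fB * bB / (fA * bA + fB * bB)
    prob[, gi] <- pB
  }
  structure(list(grid = grid, prob = prob, step_cM = step_cM,
                 error_rate = error_rate),
            class = "genoprob")
}

## Vectorized EM over all evaluation positions for one phenotype vector.
## W: n x P matrix of P(parent-B) mixing weights. Returns LOD per position.
.em_scan <- function(y, W, tol = 1e-6, max_iter = 4000, debug = FALSE) {
  n <- length(y)
  s2_0 <- mean((y - mean(y))^2)
  if (s2_0 == 0) {
    warning("constant phenotype: LOD curve is identically zero")
    return(list(lod = numeric(ncol(W)), converged = rep(TRUE, ncol(W))))
  }
  ll0 <- sum(dnorm(y, mean(y), sqrt(s2_0), log = TRUE))
  P <- ncol(W)
  G <- W                                   # initial responsibilities
  sumG <- colSums(G); sumG1 <- n - sumG
  mB <- ifelse(sumG > 1e-10, colSums(G * y) / sumG, mean(y))
  mA <- ifelse(sumG1 > 1e-10, colSums((1 - G) * y) / sumG1, mean(y))
  s2 <- colSums(G * (y - rep(mB, each = n))^2 +
                  (1 - G) * (y - rep(mA, each = n))^2) / n
  s2 <- pmax(s2, 1e-12)
  ll <- rep(-Inf, P)
  active <- rep(TRUE, P)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dA <- dnorm(y, rep(mA, each = n), rep(sqrt(s2), each = n))
    dB <- dnorm(y, rep(mB, each = n), rep(sqrt(s2), each = n))
    dim(dA) <- dim(dB) <- c(n, P)
    mix <- (1 - W) * dA + W * dB
    mix <- pmax(mix, 1e-300)
    ll_new <- colSums(log(mix))
    if (debug && any(ll_new < ll - 1e-8 & is.finite(ll)))
      stop("EM log-likelihood decreased")
    done <- abs(ll_new - ll) < tol
    ll <- ll_new
    active <- active & !done
    if (!any(active) || iter >= max_iter) break
    G <- W * dB / mix
    sumG <- colSums(G); sumG1 <- n - sumG
    mB <- ifelse(sumG > 1e-10, colSums(G * y) / sumG, mB)
    mA <- ifelse(sumG1 > 1e-10, colSums((1 - G) * y) / sumG1, mA)
    s2 <- colSums(G * (y - rep(mB, each = n))^2 +
                    (1 - G) * (y - rep(mA, each = n))^2) / n
    s2 <- pmax(s2, 1e-12)
  }
  list(lod = pmax((ll - ll0) / log(10), -1e-8), converged = !active)
}

#' Standard interval mapping by EM
#'
#' At every evaluation position, a two-component normal mixture with known
#' per-individual mixing proportions (the genotype probabilities) is fitted
#' by EM: class means plus a common variance. The LOD score is the log10
#' likelihood ratio of that mixture over a single-normal null. EM stops
#' when the log-likelihood change falls below \code{tol} or after
#' \code{max_iter} iterations (non-converged positions are flagged and the
#' last iterate reported).
#'
#' @param cross a \code{\link{ril_cross}}.
#' @param phenotype named numeric vector (one value per RIL; NAs dropped).
#' @param step_cM,error_rate grid and HMM settings, see
#'   \code{\link{calc_genoprob}}.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per position.
#' @param genoprob optionally a precomputed \code{\link{calc_genoprob}}
#'   result (must match the cross).
#' @return data.frame of class \code{lod_curve}: chrom, pos_cM, id,
#'   is_marker, lod, converged.
#' @export
scanone_em <- function(cross, phenotype, step_cM = 1, error_rate = 1e-4,
                       tol = 1e-6, max_iter = 4000, genoprob = NULL) {
  if (!inherits(cross, "ril_cross")) qg_stop("need a ril_cross", "qgscan_precondition_error")
  y <- align_strains(phenotype, cross$genotypes)
  y <- y[!is.na(y)]
  if (length(y) < 10)
    qg_stop("phenotype available for fewer than 10 RILs", "qgscan_precondition_error")
  if (is.null(genoprob)) genoprob <- calc_genoprob(cross, step_cM, error_rate)
  W <- genoprob$prob[names(y), , drop = FALSE]
  em <- .em_scan(y, W, tol, max_iter, debug = getOption("qgscan.debug", FALSE))
  out <- genoprob$grid
  out$lod <- em$lod
  out$converged <- em$converged
  if (!all(em$converged))
    warning(sprintf("%d position(s) did not converge within max_iter",
                    sum(!em$converged)))
  attr(out, "n") <- length(y)
  attr(out, "genoprob") <- genoprob
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Genome-wide LOD significance threshold by permutation
#'
#' Permutes the phenotype against the genotypes, records the genome-wide
#' maximum LOD per permutation, and returns the ceiling((1 - alpha) N)-th
#' order statistic as the threshold.
#'
#' @inheritParams scanone_em
#' @param n_permutations number of permutations (>= 100; 1,000 in the
#'   mapping study this mirrors).
#' @param alpha genome-wide significance level in (0, 1).
#' @param seed integer seed.
#' @return list of class \code{perm_threshold}: \code{threshold},
#'   \code{alpha}, \code{maxima} (all permutation maxima, reusable via
#'   \code{\link{perm_threshold_at}}).
#' @export
permutation_threshold <- function(cross, phenotype, n_permutations = 1000,
                                  alpha = 0.05, seed = 1L, step_cM = 1,
                                  error_rate = 1e-4, tol = 1e-6,
                                  max_iter = 4000, genoprob = NULL) {
  if (n_permutations < 100)
    qg_stop("need at least 100 permutations", "qgscan_config_error")
  if (alpha <= 0 || alpha >= 1)
    qg_stop("alpha must lie in (0, 1)", "qgscan_domain_error")
  y <- align_strains(phenotype, cross$genotypes)
  y <- y[!is.na(y)]
  if (is.null(genoprob)) genoprob <- calc_genoprob(cross, step_cM, error_rate)
  W <- genoprob$prob[names(y), , drop = FALSE]
  set.seed(seed)
  n <- length(y)
  maxima <- vapply(seq_len(n_permutations), function(i) {
    max(suppressWarnings(.em_scan(y[sample.int(n)], W, tol, max_iter)$lod))
  }, numeric(1))
  structure(list(threshold = perm_threshold_at(maxima, alpha),
                 alpha = alpha, maxima = maxima,
                 n_permutations = as.integer(n_permutations)),
            class = "perm_threshold")
}

#' Threshold at another level from stored permutation maxima
#'
#' @param maxima numeric vector of per-permutation genome-wide maxima (or a
#'   \code{perm_threshold} object).
#' @param alpha level in (0, 1).
#' @return the ceiling((1 - alpha) N)-th order statistic.
#' @export
perm_threshold_at <- function(maxima, alpha) {
  if (inherits(maxima, "perm_threshold")) maxima <- maxima$maxima
  if (alpha <= 0 || alpha >= 1)
    qg_stop("alpha must lie in (0, 1)", "qgscan_domain_error")
  N <- length(maxima)
  sort(maxima)[min(N, max(1L, as.integer(ceiling((1 - alpha) * N))))]
}

#' 1.5-LOD support interval around a chromosome's peak
#'
#' The peak is the position of maximum LOD on the chromosome; the support
#' interval runs to the outermost flanking positions where the curve is
#' still within \code{drop} of the peak, linearly interpolating the
#' crossing between grid points and clipping at the chromosome ends. A
#' drop of 1.5 LOD is the conventional approximate 95\% interval for RIL
#' crosses.
#'
#' @param curve a \code{\link{scanone_em}} result.
#' @param chromosome chromosome name.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return list of class \code{qtl_peak}: \code{found}, \code{chrom},
#'   \code{peak_cM}, \code{peak_lod}, \code{lo_cM}, \code{hi_cM},
#'   \code{drop}.
#' @export
lod_support_interval <- function(curve, chromosome, drop = 1.5) {
  sub <- curve[curve$chrom == chromosome, , drop = FALSE]
  if (!nrow(sub))
    qg_stop(sprintf("curve does not cover chromosome %s", chromosome),
            "qgscan_precondition_error")
  pk <- which.max(sub$lod)
  peak_lod <- sub$lod[pk]
  if (peak_lod <= 1e-6)
    return(structure(list(found = FALSE, chrom = chromosome,
                          peak_cM = NA_real_, peak_lod = peak_lod,
                          lo_cM = NA_real_, hi_cM = NA_real_, drop = drop),
                     class = "qtl_peak"))
  thr <- peak_lod - drop
  ok <- which(sub$lod >= thr)
  i_lo <- min(ok); i_hi <- max(ok)
  interp <- function(i_in, i_out) {
    ## linear crossing of the threshold between the outermost qualifying
    ## point and its non-qualifying neighbor
    x1 <- sub$pos_cM[i_out]; x2 <- sub$pos_cM[i_in]
    l1 <- sub$lod[i_out]; l2 <- sub$lod[i_in]
    x1 + (thr - l1) / (l2 - l1) * (x2 - x1)
  }
  lo <- if (i_lo > 1) interp(i_lo, i_lo - 1) else sub$pos_cM[1]
  hi <- if (i_hi < nrow(sub)) interp(i_hi, i_hi + 1) else sub$pos_cM[nrow(sub)]
  structure(list(found = TRUE, chrom = chromosome,
                 peak_cM = sub$pos_cM[pk], peak_lod = peak_lod,
                 lo_cM = lo, hi_cM = hi, drop = drop),
            class = "qtl_peak")
}

#' Phenotype summaries by genotype class at a position
#'
#' Per genotype class: count, mean, t-based 95\% confidence interval of
#' the mean, median and quartiles (linear-interpolation convention).
#' Classes with fewer than 2 observations are flagged and get no CI.
#'
#' @param phenotype numeric vector.
#' @param classes class labels aligned with \code{phenotype} (e.g. marker
#'   genotypes or the most probable HMM state).
#' @param conf confidence level (default 0.95).
#' @return data.frame, one row per class.
#' @export
genotype_group_summary <- function(phenotype, classes, conf = 0.95) {
  keep <- !is.na(phenotype) & !is.na(classes)
  phenotype <- phenotype[keep]; classes <- classes[keep]
  lv <- sort(unique(classes))
  rows <- lapply(lv, function(cl) {
    x <- phenotype[classes == cl]
    n <- length(x)
    qs <- quartiles(x)
    if (n >= 2) {
      hw <- qt(1 - (1 - conf) / 2, n - 1) * sd(x) / sqrt(n)
      ci_lo <- mean(x) - hw; ci_hi <- mean(x) + hw
    } else {
      ci_lo <- NA_real_; ci_hi <- NA_real_
    }
    data.frame(class = cl, n = n, mean = mean(x), ci_lo = ci_lo,
               ci_hi = ci_hi, q25 = qs[1], median = qs[2], q75 = qs[3],
               flagged = n < 2)
  })
  do.call(rbind, rows)
}

#' @exportS3Method base::print
print.lod_curve <- function(x, ...) {
  cat(sprintf("LOD curve: %d positions on %d chromosome(s), n = %d\n",
              nrow(x), length(unique(x$chrom)), attr(x, "n")))
  pk <- x[which.max(x$lod), ]
  cat(sprintf("  max LOD %.3f at %s:%.2f cM\n", pk$lod, pk$chrom, pk$pos_cM))
  invisible(x)
}

#' @exportS3Method base::print
print.qtl_peak <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("No peak on chromosome %s (flat curve)\n", x$chrom))
  } else {
    cat(sprintf("QTL peak on %s at %.2f cM, LOD %.3f, %.1f-LOD interval [%.2f, %.2f] cM\n",
                x$chrom, x$peak_cM, x$peak_lod, x$drop, x$lo_cM, x$hi_cM))
  }
  invisible(x)
}

#' @exportS3Method base::print
print.perm_threshold <- function(x, ...) {
  cat(sprintf("Permutation threshold (N = %d): LOD %.3f at alpha = %g\n",
              x$n_permutations, x$threshold, x$alpha))
  invisible(x)
}
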