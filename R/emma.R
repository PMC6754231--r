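## Mixed-model association for inbred panels: identity-by-state kinship,
## exact per-marker REML refits (the model y = Xb + g + e with
## Var(y) = sigma_g^2 (K + delta I), delta = sigma_e^2 / sigma_g^2),
## and permutation-based genome-wide FDR.
##
## The restricted likelihood is profiled over delta through the
## eigendecomposition of S K S (S the projection off the fixed effects):
## with eta = U' y and xi the nonzero eigenvalues,
##   lR(delta) = 0.5 [ (n-q) (log((n-q)/(2 pi)) - 1 - log sum eta_i^2/(xi_i+delta))
##                     - sum log(xi_i+delta) ].
## delta is maximized on a 100-interval grid on log10(delta) in [-5, 5]
## with root refinement of dlR/ddelta inside sign-change brackets.

DELTA_GRID <- 10^seq(-5, 5, length.out = 101)

#' Identity-by-state kinship matrix
#'
#' K[i, j] is the average allele-sharing over markers genotyped in both
#' strains: mean of 1 - |g_i - g_j| / 2. Identical strains score 1,
#' opposite homozygotes score 0.
#'
#' @param genotypes strains x markers matrix coded 0/1/2/NA.
#' @return symmetric n x n matrix with strain dimnames.
#' @export
ibs_kinship <- function(genotypes) {
  check_genotypes(genotypes)
  if (nrow(genotypes) < 2 || ncol(genotypes) < 1)
    qg_stop("need at least 2 strains and 1 marker", "qgscan_precondition_error")
  M <- !is.na(genotypes)
  shared <- tcrossprod(M * 1)
  if (any(shared == 0)) {
    idx <- which(shared == 0, arr.ind = TRUE)[1, ]
    qg_stop(sprintf("strains %s and %s share no genotyped markers",
                    rownames(genotypes)[idx[1]], rownames(genotypes)[idx[2]]),
            "qgscan_sparsity_error")
  }
  ## sum over shared markers of |g_i - g_j| via per-code indicator products
  A <- lapply(c(0, 1, 2), function(v) (!is.na(genotypes) & genotypes == v) * 1)
  absdiff <- tcrossprod(A[[1]], A[[2]]) + tcrossprod(A[[2]], A[[1]]) +
    tcrossprod(A[[2]], A[[3]]) + tcrossprod(A[[3]], A[[2]]) +
    2 * (tcrossprod(A[[1]], A[[3]]) + tcrossprod(A[[3]], A[[1]]))
  K <- 1 - absdiff / (2 * shared)
  dimnames(K) <- list(rownames(genotypes), rownames(genotypes))
  (K + t(K)) / 2
}

## Eigen-setup for one fixed-effect design: rotation of the restricted
## space (for the delta profile) and of the full space (for GLS).
.emma_prep <- function(X, K) {
  n <- nrow(X); q <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < q)
    qg_stop("singular fixed-effect design", "qgscan_rank_error")
  if (n < q + 2)
    qg_stop("need n >= rank(X) + 2 observations", "qgscan_precondition_error")
  ## IBS kinship computed across partially overlapping marker sets can be
  ## very slightly indefinite; eigenvalues within a relative tolerance of
  ## zero are clipped, anything worse is a genuine error.
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eS <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- eS$values[seq_len(n - q)]
  eK <- eigen(K, symmetric = TRUE)
  psd_tol <- 0.02 * max(abs(eK$values))
  if (min(eK$values) < -psd_tol || min(xi) < -psd_tol)
    qg_stop("kinship matrix is not positive semidefinite", "qgscan_numeric_error")
  xi <- pmax(xi, 0)
  list(n = n, q = q, UR = eS$vectors[, seq_len(n - q), drop = FALSE], xi = xi,
       UK = eK$vectors, lam = pmax(eK$values, 0), X = X)
}

.reml_loglik <- function(delta, eta2, xi, nq) {
  0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta2 / (xi + delta)))) -
           sum(log(xi + delta)))
}

.reml_dloglik <- function(delta, eta2, xi, nq) {
  v <- xi + delta
  0.5 * (nq * sum(eta2 / v^2) / sum(eta2 / v) - sum(1 / v))
}

## Grid + root-refined REML optimum in delta for one rotated phenotype.
.reml_delta <- function(eta, xi, nq, grid = DELTA_GRID) {
  eta2 <- eta^2
  d <- vapply(grid, .reml_dloglik, numeric(1), eta2 = eta2, xi = xi, nq = nq)
  cand <- c(grid[1], grid[length(grid)])
  sc <- which(d[-length(d)] > 0 & d[-1] < 0)
  for (i in sc) {
    r <- uniroot(.reml_dloglik, c(grid[i], grid[i + 1]), eta2 = eta2, xi = xi,
                 nq = nq, tol = 1e-10)
    cand <- c(cand, r$root)
  }
  ll <- vapply(cand, .reml_loglik, numeric(1), eta2 = eta2, xi = xi, nq = nq)
  best <- which.max(ll)
  list(delta = cand[best], loglik = ll[best],
       boundary = best <= 2 && length(sc) == 0)
}

#' REML fit of the one-random-effect mixed model
#'
#' Estimates the variance ratio delta = sigma_e^2 / sigma_g^2 of
#' y = X beta + g + e, Var(g) = sigma_g^2 K, Var(e) = sigma_e^2 I, by
#' restricted maximum likelihood, profiling delta through the
#' eigendecomposition of the projected covariance, a 100-interval grid on
#' log10(delta) in [-5, 5], and root refinement of the derivative inside
#' sign-change brackets.
#'
#' @param y numeric phenotype vector, no missing values.
#' @param X fixed-effect design matrix (include the intercept).
#' @param K kinship matrix, positive semidefinite, aligned with y.
#' @return list of class \code{variance_components}: \code{sigma_g2},
#'   \code{sigma_e2}, \code{delta}, \code{reml_loglik}, plus GLS
#'   coefficients \code{beta}, \code{se}, \code{t}, \code{p} (df = n -
#'   rank(X)).
#' @export
emma_reml_fit <- function(y, X = NULL, K) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X))
    qg_stop("y and X must be complete", "qgscan_precondition_error")
  prep <- .emma_prep(X, K)
  eta <- drop(crossprod(prep$UR, y))
  opt <- .reml_delta(eta, prep$xi, prep$n - prep$q)
  if (opt$boundary)
    warning("REML delta estimate lies on the search boundary (flat or monotone profile)")
  gls <- .emma_gls(y, prep, opt$delta)
  structure(list(sigma_g2 = gls$sigma_g2, sigma_e2 = opt$delta * gls$sigma_g2,
                 delta = opt$delta, reml_loglik = opt$loglik,
                 beta = gls$beta, se = gls$se, t = gls$t, p = gls$p,
                 df = prep$n - prep$q),
            class = "variance_components")
}

## GLS at fixed delta via the full-space rotation.
.emma_gls <- function(y, prep, delta) {
  w <- 1 / sqrt(prep$lam + delta)
  Xs <- (crossprod(prep$UK, prep$X)) * w
  ys <- drop(crossprod(prep$UK, y)) * w
  XtX <- crossprod(Xs)
  beta <- drop(solve(XtX, crossprod(Xs, ys)))
  rss <- sum((ys - drop(Xs %*% beta))^2)
  nq <- prep$n - prep$q
  sigma_g2 <- rss / nq
  se <- sqrt(sigma_g2 * diag(solve(XtX)))
  tstat <- beta / se
  list(beta = beta, se = se, t = tstat,
       p = 2 * pt(-abs(tstat), nq), sigma_g2 = sigma_g2)
}

#' Mixed-model association scan with exact per-marker REML refits
#'
#' For every marker passing the MAF filter, the variance components are
#' re-estimated with the marker dosage in the fixed effects (the exact
#' per-marker variant, not the single-fit approximation), and a two-sided
#' p-value is taken from the t distribution with df = n - rank(X including
#' the marker). Strains missing the marker genotype are dropped for that
#' marker's test (complete-case). Markers failing the MAF filter or with
#' zero dosage variance are flagged untested rather than tested.
#'
#' @param y named phenotype vector (one value per strain) or a long
#'   phenotype table plus \code{trait}.
#' @param genotypes strains x markers matrix coded 0/1/2/NA; heterozygote
#'   calls keep dosage 1.
#' @param K kinship matrix over at least the phenotyped strains (see
#'   \code{\link{ibs_kinship}}).
#' @param covariates optional numeric matrix of extra fixed effects, rows
#'   named by strain; the intercept is always included.
#' @param min_maf minimum minor allele frequency for a marker to be tested
#'   (default 0.05).
#' @param map optional marker map; if given, chrom/bp are carried into the
#'   result.
#' @return data.frame of class \code{association_scan}: marker, tested,
#'   n, maf, beta, se, t, p, minus_log10_p, median_ref, median_alt (allele
#'   class medians of the phenotype).
#' @export
emma_scan <- function(y, genotypes, K, covariates = NULL, min_maf = 0.05,
                      map = NULL) {
  check_genotypes(genotypes)
  y <- align_strains(y, genotypes)
  if (sum(!is.na(y)) * 2 < nrow(genotypes))
    qg_stop("phenotype missing for more than half of the strains",
            "qgscan_coverage_error")
  y <- y[!is.na(y)]
  strains <- names(y)
  g <- genotypes[strains, , drop = FALSE]
  K <- K[strains, strains]
  covar <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    covar <- covariates[strains, , drop = FALSE]
  }

  m <- ncol(g)
  out <- data.frame(marker = colnames(g), tested = FALSE, n = NA_integer_,
                    maf = NA_real_, beta = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, minus_log10_p = NA_real_,
                    median_ref = NA_real_, median_alt = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    check_marker_map(map, colnames(g))
    out$chrom <- map$chrom
    out$bp <- map$bp
  }
  for (j in seq_len(m)) {
    gj <- g[, j]
    idx <- which(!is.na(gj))
    out$n[j] <- length(idx)
    if (length(idx) < 4) next
    p_alt <- mean(gj[idx]) / 2
    out$maf[j] <- min(p_alt, 1 - p_alt)
    out$median_ref[j] <- suppressWarnings(median(y[idx][gj[idx] == 0]))
    out$median_alt[j] <- suppressWarnings(median(y[idx][gj[idx] == 2]))
    if (is.na(out$maf[j]) || out$maf[j] < min_maf || var(gj[idx]) == 0) next
    Xc <- if (is.null(covar)) NULL else covar[idx, , drop = FALSE]
    X <- cbind(1, Xc, dosage = gj[idx] / 2)
    fit <- tryCatch(suppressWarnings(emma_reml_fit(y[idx], X, K[idx, idx])),
                    qgscan_error = function(e) NULL)
    if (is.null(fit)) next
    k <- length(fit$beta)
    out$tested[j] <- TRUE
    out$beta[j] <- fit$beta[k]
    out$se[j] <- fit$se[k]
    out$t[j] <- fit$t[k]
    out$p[j] <- fit$p[k]
  }
  out$minus_log10_p <- -log10(out$p)
  attr(out, "min_maf") <- min_maf
  attr(out, "strains") <- strains
  class(out) <- c("association_scan", "data.frame")
  out
}

## Batched scan engine used by the permutation machinery: Y is an
## n x P matrix of phenotype columns over a fixed strain set. Per marker
## the eigen-rotations are computed once and shared by all columns;
## the delta optimum per column is grid argmax refined by quadratic
## interpolation in log10(delta) (the profile is smooth there).
.emma_scan_batch <- function(Y, g, K, covar = NULL, min_maf = 0.05,
                             grid = DELTA_GRID) {
  n <- nrow(Y); P <- ncol(Y); m <- ncol(g)
  lg <- log10(grid)
  pmat <- matrix(NA_real_, m, P)
  for (j in seq_len(m)) {
    gj <- g[, j]
    idx <- which(!is.na(gj))
    if (length(idx) < 4) next
    p_alt <- mean(gj[idx]) / 2
    maf <- min(p_alt, 1 - p_alt)
    if (is.na(maf) || maf < min_maf || var(gj[idx]) == 0) next
    Xc <- if (is.null(covar)) NULL else covar[idx, , drop = FALSE]
    X <- cbind(1, Xc, gj[idx] / 2)
    prep <- tryCatch(.emma_prep(X, K[idx, idx, drop = FALSE]),
                     qgscan_error = function(e) NULL)
    if (is.null(prep)) next
    nq <- prep$n - prep$q
    H <- crossprod(prep$UR, Y[idx, , drop = FALSE])   # (n-q) x P
    H2 <- H^2
    ## grid profile for all columns at once
    V <- outer(prep$xi, grid, `+`)                    # (n-q) x G
    R <- crossprod(1 / V, H2)                         # G x P: sum eta^2/(xi+delta)
    sumlog <- colSums(log(V))                         # G
    LL <- 0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(R)) - sumlog)
    gi <- max.col(t(LL), ties.method = "first")       # per column argmax
    ## quadratic refinement in log10 delta where interior
    delta <- grid[gi]
    interior <- gi > 1 & gi < length(grid)
    if (any(interior)) {
      ii <- which(interior)
      l0 <- LL[cbind(gi[ii] - 1L, ii)]
      l1 <- LL[cbind(gi[ii], ii)]
      l2 <- LL[cbind(gi[ii] + 1L, ii)]
      denom <- l0 - 2 * l1 + l2
      shift <- ifelse(abs(denom) > 1e-12, 0.5 * (l0 - l2) / denom, 0)
      shift <- pmin(pmax(shift, -0.5), 0.5)
      step <- lg[2] - lg[1]
      delta[ii] <- 10^(lg[gi[ii]] + shift * step)
    }
    ## GLS t-test of the marker coefficient per column at its delta
    w <- 1 / sqrt(outer(prep$lam, delta, `+`))        # n x P
    UX <- crossprod(prep$UK, X)                       # n x q
    UY <- crossprod(prep$UK, Y[idx, , drop = FALSE])  # n x P
    q <- ncol(X)
    tj <- numeric(P)
    for (cc in seq_len(P)) {
      Xs <- UX * w[, cc]
      ys <- UY[, cc] * w[, cc]
      XtX <- crossprod(Xs)
      bet <- solve(XtX, crossprod(Xs, ys))
      rss <- sum((ys - drop(Xs %*% bet))^2)
      sg2 <- rss / nq
      tj[cc] <- bet[q] / sqrt(sg2 * solve(XtX)[q, q])
    }
    pmat[j, ] <- 2 * pt(-abs(tj), nq)
  }
  pmat
}

#' Permutation-based genome-wide FDR for a mixed-model scan
#'
#' Phenotype labels are permuted while kinship and genotypes stay fixed,
#' and the full scan is recomputed for every permutation. For a p-value
#' cutoff t, FDR(t) = (mean permuted count of p <= t) / max(1, observed
#' count of p <= t); per-marker estimates are monotonized by step-up and
#' clipped to [0, 1]. The genome-wide max-statistic threshold at
#' \code{alpha} (the ceiling((1 - alpha) N)-th order statistic of the
#' per-permutation maximum of -log10 p) is reported alongside.
#'
#' @param scan an \code{\link{emma_scan}} result for the observed phenotype.
#' @param y,genotypes,K,covariates as passed to \code{\link{emma_scan}}.
#' @param n_permutations number of permutations (>= 100; the source study
#'   used 10,000).
#' @param seed integer seed for the permutation stream.
#' @param alpha family-wise level for the max-statistic threshold.
#' @return list of class \code{fdr_result}: \code{table} (marker, p, fdr
#'   over tested markers), \code{thresholds} (p cutoff vs FDR),
#'   \code{gw_threshold_minus_log10_p}, \code{n_permutations}, \code{alpha}.
#' @export
permutation_fdr <- function(scan, y, genotypes, K, covariates = NULL,
                            n_permutations = 1000, seed = 1L, alpha = 0.05) {
  if (n_permutations < 100)
    qg_stop("need at least 100 permutations", "qgscan_config_error")
  if (!inherits(scan, "association_scan"))
    qg_stop("scan must come from emma_scan()", "qgscan_config_error")
  strains <- attr(scan, "strains")
  y <- align_strains(y, genotypes)[strains]
  g <- genotypes[strains, , drop = FALSE]
  K <- K[strains, strains]
  covar <- if (!is.null(covariates)) as.matrix(covariates)[strains, , drop = FALSE]
  min_maf <- attr(scan, "min_maf")

  set.seed(seed)
  n <- length(y)
  P <- as.integer(n_permutations)
  Y <- cbind(y, vapply(seq_len(P), function(i) y[sample.int(n)], numeric(n)))
  pmat <- .emma_scan_batch(Y, g, K, covar, min_maf)
  tested <- !is.na(pmat[, 1])
  p_obs <- pmat[tested, 1]
  p_perm <- pmat[tested, -1, drop = FALSE]

  ord <- order(p_obs)
  p_sorted <- p_obs[ord]
  perm_all <- sort(as.numeric(p_perm))
  ## mean permuted count of p <= t, over the sorted observed cutoffs
  num <- findInterval(p_sorted, perm_all) / P
  raw <- num / seq_along(p_sorted)
  qval <- rev(cummin(rev(raw)))        # step-up monotonization
  qval <- pmin(qval, 1)
  fdr <- numeric(length(p_obs))
  fdr[ord] <- qval

  maxstat <- apply(-log10(p_perm), 2, max, na.rm = TRUE)
  kth <- min(P, max(1L, as.integer(ceiling((1 - alpha) * P))))
  gw <- sort(maxstat)[kth]

  tab <- data.frame(marker = scan$marker[tested], p = p_obs, fdr = fdr,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 thresholds = data.frame(p_cutoff = p_sorted, fdr = qval),
                 gw_threshold_minus_log10_p = gw,
                 n_permutations = P, alpha = alpha),
            class = "fdr_result")
}

#' @exportS3Method base::print
print.variance_components <- function(x, ...) {
  cat("Mixed-model REML fit\n")
  cat(sprintf("  sigma_g^2 = %.6g, sigma_e^2 = %.6g, delta = %.6g\n",
              x$sigma_g2, x$sigma_e2, x$delta))
  cat(sprintf("  restricted log-likelihood = %.6f (df = %d)\n",
              x$reml_loglik, x$df))
  invisible(x)
}

#' @exportS3Method base::print
print.association_scan <- function(x, ...) {
  tested <- sum(x$tested)
  cat(sprintf("Mixed-model association scan: %d markers (%d tested)\n",
              nrow(x), tested))
  if (tested) {
    top <- x[x$tested, ]
    top <- top[order(top$p), ][seq_len(min(5, tested)), ]
    print.data.frame(top, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @exportS3Method base::print
print.fdr_result <- function(x, ...) {
  cat(sprintf("Permutation FDR (%d permutations)\n", x$n_permutations))
  cat(sprintf("  genome-wide -log10 p threshold at alpha = %g: %.3f\n",
              x$alpha, x$gw_threshold_minus_log10_p))
  cat(sprintf("  markers with FDR <= 0.05: %d of %d\n",
              sum(x$table$fdr <= 0.05), nrow(x$table)))
  invisible(x)
}
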