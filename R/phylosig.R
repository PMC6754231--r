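## Phylogenetic signal: SNP Hamming distances, neighbor-joining trees
## (via ape, with deterministic taxon ordering and clamping of negative
## branch lengths), and maximum-likelihood Pagel's lambda with a
## likelihood-ratio test against phylogenetic independence.

#' Pairwise SNP distance matrix
#'
#' Allele-sharing Hamming proportion: the fraction of markers, genotyped in
#' both strains, at which the two genotype codes differ.
#'
#' @param genotypes strains x markers matrix coded 0/1/2/NA.
#' @return symmetric distance matrix with zero diagonal.
#' @export
snp_distance <- function(genotypes) {
  check_genotypes(genotypes)
  if (nrow(genotypes) < 3)
    qg_stop("need at least 3 strains", "qgscan_precondition_error")
  M <- !is.na(genotypes)
  shared <- tcrossprod(M * 1)
  if (any(shared == 0)) {
    idx <- which(shared == 0, arr.ind = TRUE)[1, ]
    qg_stop(sprintf("strains %s and %s share no genotyped markers",
                    rownames(genotypes)[idx[1]], rownames(genotypes)[idx[2]]),
            "qgscan_sparsity_error")
  }
  eq <- Reduce(`+`, lapply(c(0, 1, 2), function(v) {
    A <- (M & genotypes == v) * 1
    tcrossprod(A)
  }))
  D <- 1 - eq / shared
  diag(D) <- 0
  dimnames(D) <- list(rownames(genotypes), rownames(genotypes))
  (D + t(D)) / 2
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (delegated to \code{ape::nj}) on taxa sorted by
#' name, so the result is invariant to input ordering. Negative branch
#' lengths, which NJ can produce on non-additive distances, are clamped to
#' zero with the deficit moved to the sister branch, preserving path
#' lengths through the parent node.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param outgroup optional tip name; if given, the tree is rooted on that
#'   tip (the "pseudo-rooting" convention for a designated divergent
#'   strain).
#' @return an \code{ape::phylo}.
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    qg_stop("distance matrix must be symmetric", "qgscan_precondition_error")
  if (nrow(d) < 3)
    qg_stop("need at least 3 taxa", "qgscan_precondition_error")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(d)
  ## clamp negative branch lengths, moving the deficit to the sister edge
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    parent <- tr$edge[i, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), i)
    if (length(sibs))
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[i]
    tr$edge.length[i] <- 0
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      qg_stop(sprintf("outgroup '%s' is not a tip", outgroup),
              "qgscan_precondition_error")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

## Profile log-likelihood of the lambda model at a fixed lambda:
## mean and rate are maximized analytically (GLS mean, ML rate).
.lambda_profile <- function(lambda, C, y) {
  n <- length(y)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  z <- backsolve(R, cbind(y, 1), transpose = TRUE)
  yt <- z[, 1]; ot <- z[, 2]
  mu <- sum(ot * yt) / sum(ot * ot)
  rss <- sum((yt - mu * ot)^2)
  sig2 <- rss / n
  logdet <- 2 * sum(log(diag(R)))
  list(loglik = -0.5 * (n * log(2 * pi * sig2) + logdet + n),
       mean = mu, rate = sig2)
}

#' Maximum-likelihood Pagel's lambda
#'
#' Fits the multivariate-normal trait model whose covariance is the
#' Brownian shared-path-length matrix with off-diagonal entries scaled by
#' lambda (diagonal unchanged), jointly profiling the root mean and rate.
#' lambda is maximized over [0, 1] by a 101-point grid plus local
#' refinement. Significance is the likelihood-ratio statistic 2 (lnL(
#' lambda-hat) - lnL(0)) against a chi-squared with 1 df; the null of
#' lambda = 0 is complete phylogenetic independence. The boundary at
#' lambda = 0 makes this reference distribution conservative.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param tip_values named numeric vector; names must match the tips.
#' @return list of class \code{lambda_fit}: \code{lambda}, \code{rate},
#'   \code{mean}, \code{loglik}, \code{loglik0}, \code{lr_stat}, \code{p}.
#' @export
pagel_lambda <- function(tree, tip_values) {
  if (is.null(tree$edge.length))
    qg_stop("tree must carry branch lengths", "qgscan_precondition_error")
  if (is.null(names(tip_values)) ||
      !setequal(names(tip_values), tree$tip.label))
    qg_stop("tip value names must match the tree's tips", "qgscan_precondition_error")
  y <- tip_values[tree$tip.label]
  n <- length(y)
  if (n < 4)
    qg_stop("need at least 4 tips", "qgscan_precondition_error")
  if (var(y) == 0)
    qg_stop("zero-variance trait: lambda is unidentifiable", "qgscan_degenerate_error")
  C <- ape::vcv(tree)

  grid <- seq(0, 1, length.out = 101)
  ll <- vapply(grid, function(l) .lambda_profile(l, C, y)$loglik, numeric(1))
  gi <- which.max(ll)
  lo <- grid[max(1, gi - 1)]; hi <- grid[min(length(grid), gi + 1)]
  opt <- optimize(function(l) .lambda_profile(l, C, y)$loglik, c(lo, hi),
                  maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, grid[gi], 0, 1)
  cll <- vapply(cand, function(l) .lambda_profile(l, C, y)$loglik, numeric(1))
  best <- which.max(cll)
  lam <- cand[best]
  fit <- .lambda_profile(lam, C, y)
  fit0 <- .lambda_profile(0, C, y)
  lr <- max(0, 2 * (fit$loglik - fit0$loglik))
  structure(list(lambda = lam, rate = fit$rate, mean = fit$mean,
                 loglik = fit$loglik, loglik0 = fit0$loglik,
                 lr_stat = lr, p = pchisq(lr, df = 1, lower.tail = FALSE),
                 n = n),
            class = "lambda_fit")
}

#' Log-likelihood of the lambda model at fixed parameters
#'
#' Evaluates the exact multivariate-normal log-density of the tip values
#' under covariance rate * (lambda-scaled off-diagonal) and the given mean.
#' Useful for checking fitted likelihoods against a direct density
#' computation.
#'
#' @inheritParams pagel_lambda
#' @param lambda,rate,mean fixed model parameters.
#' @return scalar log-likelihood.
#' @export
lambda_loglik <- function(tree, tip_values, lambda, rate, mean) {
  y <- tip_values[tree$tip.label]
  C <- ape::vcv(tree)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  S <- rate * Cl
  R <- chol(S)
  z <- backsolve(R, y - mean, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' @exportS3Method base::print
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (rate %.4g, %d tips)\n",
              x$lambda, x$rate, x$n))
  cat(sprintf("  LR vs lambda = 0: %.3f, p = %.4g\n", x$lr_stat, x$p))
  invisible(x)
}
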