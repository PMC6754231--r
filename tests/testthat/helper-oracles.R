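# Independent oracles used to check the implementation by a different route.

# Per-pair loop IBS kinship (no matrix algebra).
oracle_ibs <- function(g) {
  n <- nrow(g)
  K <- matrix(NA_real_, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    K[i, j] <- mean(1 - abs(g[i, ok] - g[j, ok]) / 2)
  }
  K
}

# Per-pair loop Hamming-proportion distance.
oracle_snp_distance <- function(g) {
  n <- nrow(g)
  D <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    D[i, j] <- mean(g[i, ok] != g[j, ok])
  }
  D
}

# Dense grid search of the restricted likelihood (2001 points), sharing only
# the likelihood formula, not the optimizer.
oracle_reml_grid <- function(y, X, K, npts = 2001) {
  n <- length(y); q <- ncol(X)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eS <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- pmax(eS$values[seq_len(n - q)], 0)
  eta2 <- drop(crossprod(eS$vectors[, seq_len(n - q)], y))^2
  grid <- 10^seq(-5, 5, length.out = npts)
  ll <- vapply(grid, function(d) {
    nq <- n - q
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta2 / (xi + d)))) -
             sum(log(xi + d)))
  }, numeric(1))
  list(delta = grid[which.max(ll)], loglik = max(ll),
       step_log10 = 10 / (npts - 1))
}

# Exhaustive hidden-path enumeration for the two-state RIL HMM at marker
# positions (step 0): returns P(state B) at every marker for one individual.
oracle_genoprob_paths <- function(obs, pos_cM, error_rate) {
  m <- length(obs)
  r <- 2 * ((1 - exp(-2 * diff(pos_cM) / 100)) / 2) /
    (1 + 2 * ((1 - exp(-2 * diff(pos_cM) / 100)) / 2))
  emis <- function(o, s) {
    if (is.na(o) || o == 1) return(1)
    if (o == s) 1 - error_rate else error_rate
  }
  states <- as.matrix(expand.grid(rep(list(c(0, 2)), m)))
  w <- apply(states, 1, function(st) {
    p <- 0.5 * emis(obs[1], st[1])
    for (k in seq_len(m - 1)) {
      tr <- if (st[k] == st[k + 1]) 1 - r[k] else r[k]
      p <- p * tr * emis(obs[k + 1], st[k + 1])
    }
    p
  })
  vapply(seq_len(m), function(k) sum(w[states[, k] == 2]) / sum(w), numeric(1))
}

# Marker-regression LOD: (n/2) log10(RSS0/RSS1) for a fully observed marker.
oracle_marker_lod <- function(y, g) {
  keep <- !is.na(g) & g != 1
  y <- y[keep]; g <- g[keep]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2)))
  (n / 2) * log10(rss0 / rss1)
}

# Direct multivariate-normal log-density via solve() and det() (different
# route than the package's Cholesky backsolve).
oracle_mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  d <- y - mu
  -0.5 * (n * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus +
            drop(t(d) %*% solve(Sigma, d)))
}

# Hudson-style two-population differentiation estimate from genotype codes
# of homozygous strains (one allele draw per strain).
oracle_hudson_fst <- function(g, labels) {
  p <- vapply(split(seq_len(nrow(g)), labels),
              function(ix) colMeans(g[ix, , drop = FALSE]) / 2, numeric(ncol(g)))
  ns <- table(labels)
  num <- (p[, 1] - p[, 2])^2 -
    p[, 1] * (1 - p[, 1]) / (ns[1] - 1) -
    p[, 2] * (1 - p[, 2]) / (ns[2] - 1)
  den <- p[, 1] * (1 - p[, 2]) + p[, 2] * (1 - p[, 1])
  sum(num) / sum(den)
}

# Greedy windowed LD pruning, reimplemented directly with the same
# deterministic rules (highest r^2 pair first; drop lower MAF; ties drop the
# later column).
oracle_ld_prune <- function(g, window_size, step, r2_threshold) {
  maf <- apply(g, 2, function(col) {
    p <- mean(col, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  removed <- rep(FALSE, ncol(g))
  start <- 1
  repeat {
    win <- seq(start, min(start + window_size - 1, ncol(g)))
    repeat {
      live <- win[!removed[win]]
      if (length(live) < 2) break
      best <- c(NA, NA); bestr <- -1
      for (i in seq_along(live)) for (j in seq_along(live)) if (i < j) {
        r2 <- suppressWarnings(cor(g[, live[i]], g[, live[j]],
                                   use = "pairwise.complete.obs"))^2
        if (is.finite(r2) && r2 > bestr) { bestr <- r2; best <- c(live[i], live[j]) }
      }
      if (bestr <= r2_threshold) break
      a <- best[1]; b <- best[2]
      drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
      removed[drop] <- TRUE
    }
    if (start + window_size - 1 >= ncol(g)) break
    start <- start + step
  }
  colnames(g)[!removed]
}
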