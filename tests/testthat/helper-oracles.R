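# Independent oracles and small fixtures shared across test files.
# Oracles are deliberately naive (explicit loops, direct formulas) so they
# cannot share code paths with the implementation they check.

# Brute-force BH step-up: sort, apply n/i * p, cumulative minimum from the
# largest p down, map back.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Explicit sandwich variance: per-PSU score totals, centered within stratum,
# n_h/(n_h-1) factor, bread = (X'WX)^{-1}. Written with plain loops.
sandwich_oracle <- function(y, X, w, stratum, psu) {
  XtWX <- t(X) %*% diag(w) %*% X
  A <- solve(XtWX)
  beta <- A %*% t(X) %*% diag(w) %*% y
  e <- y - X %*% beta
  G <- matrix(0, ncol(X), ncol(X))
  for (h in unique(stratum)) {
    psus <- unique(psu[stratum == h])
    Z <- matrix(0, length(psus), ncol(X))
    for (ci in seq_along(psus)) {
      rows <- which(stratum == h & psu == psus[ci])
      for (r in rows) Z[ci, ] <- Z[ci, ] + w[r] * e[r] * X[r, ]
    }
    zbar <- colMeans(Z)
    nh <- length(psus)
    for (ci in seq_len(nh)) {
      dz <- Z[ci, ] - zbar
      G <- G + (nh / (nh - 1)) * outer(dz, dz)
    }
  }
  list(beta = drop(beta), vcov = A %*% G %*% A)
}

# High-precision direct ACAT evaluation.
acat_oracle <- function(p, w = rep(1 / length(p), length(p))) {
  T_stat <- sum(w * tan((0.5 - p) * pi))
  0.5 - atan(T_stat) / pi
}

# All set partitions of n elements as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1
    if (i > n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (g in seq_len(k + 1)) rec(c(labels, g), max(k, g))
  }
  rec(integer(0), 0)
  out
}

# Direct evaluation of Barber's bipartite modularity for a given joint
# partition (rows first, then columns).
barber_Q <- function(W, labels) {
  R <- nrow(W); C <- ncol(W)
  tot <- sum(W)
  k <- rowSums(W); d <- colSums(W)
  q <- 0
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      if (labels[i] == labels[R + j])
        q <- q + W[i, j] - k[i] * d[j] / tot
    }
  }
  q / tot
}

# NODF by naive enumeration over all ordered pairs.
nodf_oracle <- function(B) {
  score_pairs <- function(M) {
    f <- rowSums(M)
    n <- nrow(M)
    contrib <- c()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j) {
          a <- which.max(c(f[i], f[j]))
          hi <- c(i, j)[a]; lo <- c(i, j)[-a]
          contrib <- c(contrib,
                       if (f[hi] > f[lo])
                         100 * sum(M[hi, ] & M[lo, ]) / f[lo] else 0)
        }
      }
    }
    contrib
  }
  v <- c(score_pairs(B), score_pairs(t(B)))
  mean(v)
}

# A small fixed survey design: 3 strata x 2 PSUs, 5 subjects per PSU.
tiny_design_data <- function(seed = 42) {
  set.seed(seed)
  n <- 30
  stratum <- rep(1:3, each = 10)
  psu <- rep(1:6, each = 5)
  w <- runif(n, 0.5, 2.5)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n) * (1 + 0.3 * (stratum == 2))
  list(y = y, X = cbind(`(Intercept)` = 1, x = x), w = w,
       stratum = stratum, psu = psu,
       design = svy_design(stratum, psu, w))
}

# Compact cohort used by scan-level tests: few phenotypes and metabolites.
small_registry <- function() {
  list(
    phenotype_spec("dur", "Duration", "continuous", mean = 7, sd = 1),
    phenotype_spec("pill", "Insomnia", "binary", prevalence = 0.3),
    phenotype_spec("bed", "Timing", "circular", mean_time = 23,
                   concentration = 8))
}

small_mets <- function(n = 8, n_xeno = 2, seed = 5) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n)) {
    nm <- sprintf("m%02d", i)
    if (i <= n_xeno) {
      out[[i]] <- metabolite_spec(nm, "Xenobiotics", "Xeno sub1",
                                  xenobiotic = TRUE,
                                  detection_limit_quantile = 0.2)
    } else {
      sp <- c("Lipid", "Amino Acid")[1 + i %% 2]
      out[[i]] <- metabolite_spec(nm, sp, paste(sp, "sub", 1 + i %% 2),
                                  missing_rate = 0.1,
                                  missingness_covariate_slope = 0.5)
    }
  }
  out
}
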