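# Independent oracles and small fixture builders shared across tests.

# Brute-force agglomerative Ward clustering (Lance-Williams update on
# squared Euclidean distances, heights reported on the distance scale as
# hclust method "ward.D2" does). O(n^3); for cross-checking only.
ward_oracle <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  active <- seq_len(n)
  id <- -seq_len(n)                     # hclust-style ids
  size <- rep(1L, n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)[-length(active)]) {
      for (b in (a + 1L):length(active)) {
        if (d2[active[a], active[b]] < bd - 1e-12) {
          bd <- d2[active[a], active[b]]; best <- c(a, b)
        }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    merges[m, ] <- sort(c(id[i], id[j]))
    heights[m] <- sqrt(bd)
    # Lance-Williams Ward update against every other active cluster
    for (k in active) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((size[i] + size[k]) * d2[i, k] + (size[j] + size[k]) * d2[j, k] -
           size[k] * bd) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    id[i] <- m
    active <- active[active != j]
  }
  list(merge = merges, height = heights)
}

# Eigen-based PLS2 oracle: per deflation step the weight vector is the
# dominant eigenvector of Xd' Yd Yd' Xd; scores/loadings/deflation as in
# NIPALS. Independent of the package's iterative path.
pls_eigen_oracle <- function(Xc, Yc, K) {
  Xd <- as.matrix(Xc); Yd <- as.matrix(Yc)
  p <- ncol(Xd)
  W <- matrix(0, p, K); P <- matrix(0, p, K); Tm <- matrix(0, nrow(Xd), K)
  for (k in seq_len(K)) {
    M <- crossprod(crossprod(Yd, Xd))      # Xd' Yd Yd' Xd
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    jm <- which.max(abs(w)); if (w[jm] < 0) w <- -w
    tt <- as.vector(Xd %*% w)
    pv <- crossprod(Xd, tt) / sum(tt^2)
    q <- crossprod(Yd, tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pv)
    Yd <- Yd - tcrossprod(tt, q)
    W[, k] <- w; P[, k] <- pv; Tm[, k] <- tt
  }
  list(W = W, P = P, T = Tm)
}

# Equal-prior Mahalanobis-distance classifier.
mahalanobis_oracle <- function(scores, means, covmat) {
  d <- apply(means, 1L, function(mu) {
    stats::mahalanobis(scores, mu, covmat)
  })
  rownames(means)[apply(matrix(d, nrow = nrow(scores)), 1L, which.min)]
}

# Agreement of two partitions up to label permutation.
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Small preprocessed reference dataset, cached per test run.
fresh_reference <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache)) {
      cache <<- preprocess_spectra(simulate_dataset(reference_design(seed = seed)))
    }
    cache
  }
})

# Tiny 2-class spectra set for fast mechanics tests.
toy_two_fluids <- function(n_donors = 6, replicates = 3, seed = 5) {
  d <- dataset_design(fluids = c("urine", "sweat"), n_donors = n_donors,
                      replicates = replicates, seed = seed)
  preprocess_spectra(simulate_dataset(d))
}
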