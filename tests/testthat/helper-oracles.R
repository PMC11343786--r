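# Independent oracles and small fixtures used across the suite.
# Everything here is deliberately brute-force / closed-form and shares no
# code with the implementation paths it checks.

# Gaussian blobs with known labels.
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  centers <- as.matrix(centers)
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[c, ], n_per, ncol(centers), byrow = TRUE)
    }))
    list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# Global k-means optimum by enumeration of all assignments of n points into
# k (non-empty) clusters; WCSS = sum of squared deviations from cluster
# means.  Feasible for n <= 10, k <= 3.
brute_force_kmeans_wcss <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 12, k <= 3)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      w <- 0
      for (c in seq_len(k)) {
        rows <- X[assign == c, , drop = FALSE]
        w <- w + sum(sweep(rows, 2, colMeans(rows))^2)
      }
      if (w < best) best <- w
    }
    # next assignment in base-k counting
    i <- 1L
    while (i <= n) {
      if (assign[i] < k) {
        assign[i] <- assign[i] + 1L
        break
      }
      assign[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# ARI by direct pair counting over all C(n,2) pairs.
pair_count_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (same_a && !same_b) s10 <- s10 + 1
    else if (!same_a && same_b) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  2 * (s11 * s00 - s10 * s01) /
    ((s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of P(X = x) over all tables as or less probable than the observed one.
hypergeom_fisher_p <- function(tab) {
  m <- sum(tab[1, ]) # successes in population
  nn <- sum(tab[2, ])
  kk <- sum(tab[, 1]) # draws
  x_obs <- tab[1, 1]
  support <- max(0, kk - nn):min(kk, m)
  probs <- stats::dhyper(support, m, nn, kk)
  p_obs <- stats::dhyper(x_obs, m, nn, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Build a binary-outcome fixture with prescribed per-cluster counts,
# available-case denominators and total cluster sizes.
make_binary_fixture <- function(counts, denoms, sizes) {
  labels <- rep(seq_along(sizes), sizes)
  outcome <- unlist(lapply(seq_along(sizes), function(c) {
    c(rep(1L, counts[c]), rep(0L, denoms[c] - counts[c]),
      rep(NA_integer_, sizes[c] - denoms[c]))
  }))
  data.frame(outcome = outcome, cluster = labels)
}
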