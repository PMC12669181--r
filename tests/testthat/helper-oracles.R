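# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph) so they can serve as
# ground truth: Heap's algorithm for permutations, textbook rank-correlation
# formulas, Floyd-Warshall shortest paths with explicit path counting, and
# direct covariance algebra for the microcircuit generator.

# All permutations of 1..n via Heap's algorithm (iterative).
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  out[1, ] <- a
  c_ <- rep(0L, n)
  i <- 1L
  row <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# Average-rank Spearman rho from the Pearson formula written out by hand.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt(sum(rx^2) - n * mean(rx)^2) * sqrt(sum(ry^2) - n * mean(ry)^2)
  num / den
}

# Exact two-tailed permutation p by looping over every ordering.
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  perms <- heap_permutations(n)
  obs <- abs(oracle_spearman_rho(x, y))
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    if (abs(oracle_spearman_rho(x, y[perms[r, ]])) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / nrow(perms)
}

# --- small-graph oracles -----------------------------------------------

# Build a coact_network directly from an edge tibble (testing constructor).
make_network <- function(regions, edges, alpha = 0.05) {
  edges <- tibble::as_tibble(edges)
  if (!"p" %in% names(edges)) edges$p <- 0
  structure(
    list(
      nodes = tibble::tibble(region = regions),
      edges = edges[, c("from", "to", "rho", "p")],
      alpha = alpha,
      n_possible = length(regions) * (length(regions) - 1) / 2,
      n_animals = NA_integer_
    ),
    class = "coact_network"
  )
}

# Random weighted graph for oracle comparisons.
random_network <- function(n_nodes, p_edge = 0.45, seed = 1) {
  set.seed(seed)
  regions <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(seq_len(n_nodes), 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  w <- runif(nrow(pairs), 0.15, 0.95) * sample(c(-1, 1), nrow(pairs), TRUE)
  make_network(regions, tibble::tibble(
    from = regions[pairs[, 1]], to = regions[pairs[, 2]], rho = w
  ))
}

# Adjacency matrices (weight and length) from a network.
oracle_adjacency <- function(network) {
  regions <- network$nodes$region
  n <- length(regions)
  W <- matrix(0, n, n, dimnames = list(regions, regions))
  for (r in seq_len(nrow(network$edges))) {
    i <- network$edges$from[r]; j <- network$edges$to[r]
    W[i, j] <- W[j, i] <- abs(network$edges$rho[r])
  }
  W
}

# All-pairs shortest-path distances (edge length 1/|w|) by Floyd-Warshall.
oracle_distances <- function(network) {
  W <- oracle_adjacency(network)
  n <- nrow(W)
  D <- matrix(Inf, n, n, dimnames = dimnames(W))
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Number of distinct shortest paths between every pair, by dynamic
# programming over nodes ordered by distance from the source.
oracle_path_counts <- function(network, D = oracle_distances(network)) {
  W <- oracle_adjacency(network)
  L <- ifelse(W > 0, 1 / W, Inf)
  n <- nrow(W)
  eps <- 1e-10
  sigma <- matrix(0, n, n, dimnames = dimnames(W))
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    cnt <- rep(0, n)
    cnt[s] <- 1
    for (t in ord) {
      if (t == s || is.infinite(D[s, t])) next
      for (v in seq_len(n)) {
        if (L[v, t] < Inf && abs(D[s, v] + L[v, t] - D[s, t]) < eps) {
          cnt[t] <- cnt[t] + cnt[v]
        }
      }
    }
    sigma[s, ] <- cnt
  }
  sigma
}

# Betweenness with fractional credit for tied shortest paths.
oracle_betweenness <- function(network) {
  D <- oracle_distances(network)
  sigma <- oracle_path_counts(network, D)
  n <- nrow(D)
  eps <- 1e-10
  b <- rep(0, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s >= t || is.infinite(D[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (abs(D[s, v] + D[v, t] - D[s, t]) < eps && sigma[s, t] > 0) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  setNames(b, rownames(D))
}

oracle_efficiency <- function(network) {
  D <- oracle_distances(network)
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

# Transitivity by exhaustive triangle / connected-triplet enumeration.
oracle_transitivity <- function(network) {
  A <- (oracle_adjacency(network) > 0) * 1
  n <- nrow(A)
  triangles <- 0
  triplets <- 0
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    triplets <- triplets + choose(k, 2)
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && A[nb[a], nb[b]] == 1) triangles <- triangles + 1
      }
    }
  }
  if (triplets == 0) return(0)
  # each triangle is counted once per corner vertex = 3 times total
  triangles / triplets
}

# Direct evaluation of Newman modularity on |w| weights.
oracle_modularity <- function(network, membership) {
  W <- oracle_adjacency(network)
  m2 <- sum(W) # twice total weight
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# Chi-square statistic by direct (O - E)^2 / E summation.
oracle_chisq <- function(counts) {
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - E)^2 / E)
}

# Microcircuit covariance algebra: pairwise moments derived equation by
# equation (independent of the generator's reduced-form matrix).
oracle_microcircuit_cov <- function(a1, a2, b1, b2, b3, s = c(1, 1, 1)) {
  v_p <- 1
  c_mc_p <- a1 * v_p
  v_mc <- a1^2 * v_p + s[1]^2
  c_pvgl_p <- a2 * c_mc_p
  c_pvgl_mc <- a2 * v_mc
  v_pvgl <- a2^2 * v_mc + s[2]^2
  c_gc_p <- b1 * c_mc_p + b2 * c_pvgl_p + b3 * v_p
  c_gc_mc <- b1 * v_mc + b2 * c_pvgl_mc + b3 * c_mc_p
  c_gc_pvgl <- b1 * c_pvgl_mc + b2 * v_pvgl + b3 * c_pvgl_p
  v_gc <- b1^2 * v_mc + b2^2 * v_pvgl + b3^2 * v_p +
    2 * b1 * b2 * c_pvgl_mc + 2 * b1 * b3 * c_mc_p + 2 * b2 * b3 * c_pvgl_p +
    s[3]^2
  m <- matrix(c(
    v_mc, c_mc_p, c_pvgl_mc, c_gc_mc,
    c_mc_p, v_p, c_pvgl_p, c_gc_p,
    c_pvgl_mc, c_pvgl_p, v_pvgl, c_gc_pvgl,
    c_gc_mc, c_gc_p, c_gc_pvgl, v_gc
  ), 4, 4, dimnames = list(
    c("MC", "PV_H", "PV_GL", "GC"), c("MC", "PV_H", "PV_GL", "GC")
  ))
  m
}

# Correlation-matrix fixture with chosen significant pairs; p = 1e-6 for
# listed pairs, 0.9 otherwise, rho as given (default 0.8).
make_cormat <- function(regions, sig_pairs, rho = 0.8, n = 7) {
  k <- length(regions)
  R <- matrix(0.05, k, k, dimnames = list(regions, regions))
  P <- matrix(0.9, k, k, dimnames = list(regions, regions))
  if (length(rho) == 1) rho <- rep(rho, nrow(sig_pairs))
  for (r in seq_len(nrow(sig_pairs))) {
    i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
    R[i, j] <- R[j, i] <- rho[r]
    P[i, j] <- P[j, i] <- 1e-6
  }
  diag(R) <- 1
  diag(P) <- 0
  structure(
    list(
      regions = regions, rho = R, p = P, n = n, p_method = "t",
      dropped_animals = character(), constant_regions = character()
    ),
    class = "coact_cormat"
  )
}
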