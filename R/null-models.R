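# Chance calibration for network metrics: diagonal-preserving shuffles of
# the correlation matrix (the null ensemble), ring-lattice references, and
# normalization of raw metrics by the null-ensemble mean so networks of
# different densities can be compared.

#' Diagonal-preserving shuffle null ensemble
#'
#' Generates `B` null correlation matrices by shuffling the off-diagonal
#' structure of the source matrix while keeping the main diagonal intact:
#' each member places the observed upper-triangle `(rho, p)` pairs at a
#' uniformly permuted set of region-pair positions and mirrors them, so
#' every member is symmetric, its diagonal equals the source's, and its
#' off-diagonal value multiset is exactly the source's. Because the p-values
#' travel with their correlations, thresholding a member at any alpha keeps
#' the observed edge count while decoupling which regions the edges join —
#' the chance reference used for metric normalization and hub significance.
#'
#' @param cormat A [spearman_matrix()] result.
#' @param B Number of shuffled members; default 100.
#' @param seed Integer seed.
#' @return An object of class `null_ensemble`: list with `source`, `B`,
#'   `perms` (B x n_pairs position-permutation matrix), `rho` and `p`
#'   (lists of B matrices), `seed`.
#' @export
shuffle_null_models <- function(cormat, B = 100L, seed = 1L) {
  stopifnot(inherits(cormat, "coact_cormat"))
  B <- as.integer(B)
  if (B < 1L) abort("`B` must be at least 1.")
  k <- length(cormat$regions)
  up <- upper.tri(cormat$rho)
  n_pairs <- sum(up)
  perms <- with_seed(derive_seed(seed, "shuffle-null"), {
    t(replicate(B, sample.int(n_pairs)))
  })
  rho <- vector("list", B)
  p <- vector("list", B)
  for (b in seq_len(B)) {
    pi_ <- perms[b, ]
    r <- cormat$rho
    q <- cormat$p
    r[up] <- cormat$rho[up][pi_]
    q[up] <- cormat$p[up][pi_]
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    rho[[b]] <- r
    p[[b]] <- q
  }
  structure(
    list(source = cormat, B = B, perms = perms, rho = rho, p = p, seed = seed),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %d diagonal-preserving shuffles of a %d-region matrix\n",
    x$B, length(x$source$regions)
  ))
  invisible(x)
}

# A coact_cormat view of ensemble member b.
null_member_cormat <- function(ensemble, b) {
  src <- ensemble$source
  structure(
    list(
      regions = src$regions, rho = ensemble$rho[[b]], p = ensemble$p[[b]],
      n = src$n, p_method = src$p_method, dropped_animals = character(),
      constant_regions = src$constant_regions
    ),
    class = "coact_cormat"
  )
}

#' Thresholded network for one null-ensemble member
#'
#' @param ensemble A [shuffle_null_models()] result.
#' @param b Member index in `1..B`.
#' @param alpha Significance threshold (use the observed network's alpha).
#' @return A `coact_network`.
#' @export
null_member_network <- function(ensemble, b, alpha = 0.05) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  build_network(null_member_cormat(ensemble, b), alpha = alpha)
}

#' Node-centrality distributions under the shuffle null
#'
#' Thresholds every ensemble member at `alpha` and computes node
#' centralities, giving the null distributions used by [detect_hubs()].
#'
#' @inheritParams null_member_network
#' @return A tibble: `member`, `region`, `degree`, `strength`,
#'   `betweenness`.
#' @export
null_node_metrics <- function(ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  purrr::map_dfr(seq_len(ensemble$B), function(b) {
    net <- null_member_network(ensemble, b, alpha = alpha)
    dplyr::mutate(node_centralities(net), member = b, .before = 1L)
  })
}

#' Ring-lattice reference network
#'
#' Builds a lattice with the same node and edge count as the input network:
#' nodes are placed on a ring (ordering shuffled under the seed) and edges
#' fill the nearest ring distances first. The observed `|rho|` weights are
#' assigned in decreasing order to the shortest ring distances, giving the
#' highly clustered, long-path reference used to normalize clustering.
#'
#' @param network A `coact_network` with at least 1 edge.
#' @param seed Integer seed for the ring ordering.
#' @return A `coact_network` whose edges carry the reassigned weights.
#' @export
lattice_reference <- function(network, seed = 1L) {
  stopifnot(inherits(network, "coact_network"))
  m <- nrow(network$edges)
  if (m < 1L) abort("need at least 1 edge.")
  nodes <- network$nodes$region
  n <- length(nodes)
  ring <- with_seed(derive_seed(seed, "lattice"), sample(nodes))
  # candidate edges by increasing ring distance
  cand <- purrr::map_dfr(seq_len(floor(n / 2)), function(d) {
    i <- seq_len(n)
    j <- ((i - 1L + d) %% n) + 1L
    keep <- if (2L * d == n) i < j else rep(TRUE, n)
    tibble::tibble(from = ring[i[keep]], to = ring[j[keep]], dist = d)
  })
  if (m > nrow(cand)) abort("edge count exceeds the complete graph.")
  sel <- cand[seq_len(m), ]
  w <- sort(abs(network$edges$rho), decreasing = TRUE)
  structure(
    list(
      nodes = network$nodes,
      edges = tibble::tibble(
        from = sel$from, to = sel$to, rho = w, p = 0
      ),
      alpha = network$alpha,
      n_possible = network$n_possible,
      n_animals = network$n_animals
    ),
    class = "coact_network"
  )
}

# Registry of network-level metrics shared by normalization and comparison.
network_metric_fun <- function(metric = c(
                                 "efficiency", "clustering", "modularity",
                                 "mean_strength"
                               )) {
  metric <- match.arg(metric)
  switch(metric,
    efficiency = function(net, seed) global_efficiency(net),
    clustering = function(net, seed) {
      suppressMessages(global_clustering(net))
    },
    modularity = function(net, seed) {
      suppressWarnings(louvain_partition(net, seed = seed))$modularity_q
    },
    mean_strength = function(net, seed) mean_strength(net)
  )
}

#' Normalize a network metric by its shuffle-null mean
#'
#' Computes the metric on the observed network and on every thresholded
#' null-ensemble member; the normalized value is `raw / mean(null)`. When a
#' lattice reference is supplied its metric value is reported alongside,
#' together with the lattice-referenced ratio where applicable.
#'
#' @param network A `coact_network`.
#' @param ensemble A [shuffle_null_models()] result built from the same
#'   correlation matrix and thresholded at the network's alpha.
#' @param metric One of `"efficiency"`, `"clustering"`, `"modularity"`,
#'   `"mean_strength"`.
#' @param lattice Optional [lattice_reference()] network.
#' @param seed Seed for metrics that need one (Louvain modularity).
#' @return A one-row tibble: `metric`, `raw`, `random_mean`, `lattice_value`,
#'   `normalized` (`raw / random_mean`), `lattice_ratio` (`raw /
#'   lattice_value`). Division by zero yields `NA` with a message.
#' @export
normalize_metric <- function(network, ensemble, metric, lattice = NULL,
                             seed = 1L) {
  stopifnot(inherits(network, "coact_network"))
  f <- network_metric_fun(metric)
  raw <- f(network, derive_seed(seed, "norm-raw"))
  nulls <- vapply(seq_len(ensemble$B), function(b) {
    suppressMessages(f(
      null_member_network(ensemble, b, alpha = network$alpha),
      derive_seed(seed, "norm-null", b)
    ))
  }, numeric(1))
  random_mean <- mean(nulls, na.rm = TRUE)
  normalized <- if (is.finite(random_mean) && random_mean != 0) {
    raw / random_mean
  } else {
    inform(sprintf("null-ensemble mean of %s is 0: normalized value undefined.", metric))
    NA_real_
  }
  lattice_value <- lattice_ratio <- NA_real_
  if (!is.null(lattice)) {
    lattice_value <- suppressMessages(f(lattice, derive_seed(seed, "norm-lattice")))
    lattice_ratio <- if (is.finite(lattice_value) && lattice_value != 0) {
      raw / lattice_value
    } else {
      NA_real_
    }
  }
  tibble::tibble(
    metric = metric, raw = raw, random_mean = random_mean,
    lattice_value = lattice_value, normalized = normalized,
    lattice_ratio = lattice_ratio
  )
}
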