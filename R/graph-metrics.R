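# Graph-theoretical characterization of co-activation networks. Sign
# convention: all distance- and modularity-based computations use |rho| as
# the connection weight (a signed sum would let negative edges cancel
# positive ones and break the "higher = more central" reading); the sign is
# kept in the data model and used by edge_composition() and the
# excitatory/inhibitory interpretation only. Path lengths are 1 / |rho|, so
# stronger correlations are shorter and global efficiency stays in [0, 1].

#' Node centralities of a co-activation network
#'
#' Degree (incident significant edges), strength (sum of absolute edge
#' weights) and weighted betweenness centrality (number of shortest paths
#' through a node, with fractional credit for tied shortest paths, edge
#' length `1 / |rho|`). Isolated regions get zeros.
#'
#' @param network A `coact_network`.
#' @return A tibble: `region`, `degree`, `strength`, `betweenness`.
#' @export
node_centralities <- function(network) {
  g <- as_coact_igraph(network)
  betw <- if (igraph::ecount(g) > 0) {
    igraph::betweenness(g, weights = igraph::E(g)$length)
  } else {
    rep(0, igraph::vcount(g))
  }
  tibble::tibble(
    region = igraph::V(g)$name,
    degree = unname(as.integer(igraph::degree(g))),
    strength = unname(igraph::strength(g, weights = igraph::E(g)$weight)),
    betweenness = unname(as.numeric(betw))
  )
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance with
#' edge lengths `1 / |rho|`; disconnected pairs contribute 0. Because
#' `|rho| <= 1`, every inverse distance is at most 1 and the result lies in
#' `[0, 1]`.
#'
#' @param network A `coact_network` with at least 2 nodes.
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(network) {
  g <- as_coact_igraph(network)
  n <- igraph::vcount(g)
  if (n < 2L) abort("need at least 2 nodes.")
  if (igraph::ecount(g) == 0L) return(0)
  d <- igraph::distances(g, weights = igraph::E(g)$length)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global clustering coefficient (transitivity)
#'
#' The probability that two regions connected to a common neighbor are also
#' connected: `3 * triangles / connected triplets` on the binarized edge
#' set. Networks with no connected triplet return 0 with a message.
#'
#' @param network A `coact_network` with at least 3 nodes.
#' @return A number in `[0, 1]`.
#' @export
global_clustering <- function(network) {
  g <- as_coact_igraph(network)
  if (igraph::vcount(g) < 3L) abort("need at least 3 nodes.")
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) {
    inform("no connected triplets: clustering reported as 0.")
    return(0)
  }
  tr
}

#' Mean network strength
#'
#' Arithmetic mean of node strengths, used as an overall-efficiency summary
#' alongside global efficiency.
#'
#' @param network A `coact_network`.
#' @return A non-negative number.
#' @export
mean_strength <- function(network) {
  mean(node_centralities(network)$strength)
}

#' Louvain community detection with a resolution parameter
#'
#' Runs the Louvain algorithm on absolute edge weights at the given
#' resolution. For comparability across resolutions, the reported modularity
#' `Q` is always evaluated at resolution 1 on the returned assignment. Node
#' order is shuffled under the seed, making the (order-dependent) greedy
#' algorithm reproducible.
#'
#' @param network A `coact_network`.
#' @param resolution Positive resolution of the quality function; default 1.
#' @param seed Integer seed for the node-order shuffle.
#' @param binarize Run on unit weights instead of `|rho|`; default FALSE.
#' @return An object of class `coact_partition`: list with `assignment`
#'   (tibble `region`, `module`), `modularity_q`, `resolution`, `n_modules`,
#'   and `n_modules_connected` (modules containing at least one non-isolated
#'   region, the count used for resolution selection).
#' @export
louvain_partition <- function(network, resolution = 1, seed = 1L,
                              binarize = FALSE) {
  check_positive_scalar(resolution, "resolution")
  g <- as_coact_igraph(network)
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) {
    warn("edgeless network: every region is its own module, Q = 0.")
    assignment <- tibble::tibble(
      region = igraph::V(g)$name, module = seq_len(n)
    )
    return(structure(
      list(
        assignment = assignment, modularity_q = 0, resolution = resolution,
        n_modules = n, n_modules_connected = 0L
      ),
      class = "coact_partition"
    ))
  }
  w_attr <- if (binarize) NULL else igraph::E(g)$weight
  res <- with_seed(seed, {
    ord <- sample.int(n)
    gp <- igraph::permute(g, ord)
    cl <- igraph::cluster_louvain(
      gp,
      weights = if (binarize) NA else igraph::E(gp)$weight,
      resolution = resolution
    )
    memb <- igraph::membership(cl)
    # map back to original vertex order
    memb[match(igraph::V(g)$name, igraph::V(gp)$name)]
  })
  memb <- as.integer(factor(res))
  q <- igraph::modularity(g, memb, weights = w_attr)
  deg <- igraph::degree(g)
  structure(
    list(
      assignment = tibble::tibble(region = igraph::V(g)$name, module = memb),
      modularity_q = q,
      resolution = resolution,
      n_modules = dplyr::n_distinct(memb),
      n_modules_connected = dplyr::n_distinct(memb[deg > 0])
    ),
    class = "coact_partition"
  )
}

#' @export
print.coact_partition <- function(x, ...) {
  cat(sprintf(
    "<coact_partition> %d modules (Q = %.3f at resolution 1; run at resolution %g)\n",
    x$n_modules, x$modularity_q, x$resolution
  ))
  invisible(x)
}

#' @describeIn louvain_partition Tidy module assignment.
#' @param x A `coact_partition`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.coact_partition <- function(x, ...) {
  x$assignment
}

#' Select the Louvain resolution by bootstrap module-count stability
#'
#' For each candidate resolution, rebuilds the network on `B` bootstrap
#' tables (animals resampled with replacement, within group when a group
#' column is present), runs Louvain, and records the number of modules among
#' connected regions. The selected resolution is the one whose modal module
#' count recurs most often across bootstrap samples; ties are broken toward
#' the resolution closest to 1.
#'
#' @param table Activation table for one group.
#' @param grid Candidate resolutions (positive reals).
#' @param B Number of bootstrap samples, at least 10.
#' @param seed Integer seed.
#' @param alpha Edge significance threshold.
#' @param id_cols Non-region columns.
#' @return A list: `resolution`, `modal_module_count`, `frequency` (relative
#'   frequency of the modal count), and `summary` (tibble over the grid).
#' @export
select_resolution <- function(table, grid = c(0.5, 1, 1.3), B = 100L,
                              seed = 1L, alpha = 0.05,
                              id_cols = c("animal_id", "group")) {
  if (length(grid) == 0L || any(grid <= 0)) {
    abort("`grid` must be a non-empty vector of positive resolutions.")
  }
  B <- as.integer(B)
  if (B < 10L) abort("`B` must be at least 10.")
  grp <- if ("group" %in% names(table)) table$group else rep("all", nrow(table))
  counts <- with_seed(derive_seed(seed, "resolution-bootstrap"), {
    purrr::map(seq_len(B), function(b) {
      idx <- unlist(lapply(split(seq_len(nrow(table)), grp), function(i) {
        sample(i, length(i), replace = TRUE)
      }), use.names = FALSE)
      boot <- table[idx, , drop = FALSE]
      if ("animal_id" %in% names(boot)) {
        boot$animal_id <- sprintf("bs%03d", seq_len(nrow(boot)))
      }
      cm <- suppressMessages(spearman_matrix(boot, id_cols = id_cols))
      net <- build_network(cm, alpha = alpha)
      if (nrow(net$edges) == 0L) return(rep(NA_integer_, length(grid)))
      vapply(seq_along(grid), function(gi) {
        p <- suppressWarnings(louvain_partition(
          net,
          resolution = grid[gi],
          seed = derive_seed(seed, "resolution-louvain", b * 1000L + gi)
        ))
        p$n_modules_connected
      }, integer(1))
    })
  })
  counts <- do.call(rbind, counts)
  if (all(is.na(counts))) abort("all bootstrap networks were edgeless.")
  summary <- purrr::map_dfr(seq_along(grid), function(gi) {
    x <- counts[, gi]
    x <- x[!is.na(x)]
    tab <- table(x)
    modal <- as.integer(names(tab)[which.max(tab)])
    tibble::tibble(
      resolution = grid[gi],
      modal_module_count = modal,
      frequency = max(tab) / length(x)
    )
  })
  best <- summary |>
    dplyr::arrange(
      dplyr::desc(.data$frequency), abs(.data$resolution - 1), .data$resolution
    ) |>
    dplyr::slice(1)
  list(
    resolution = best$resolution,
    modal_module_count = best$modal_module_count,
    frequency = best$frequency,
    summary = summary
  )
}

#' Hub detection against a shuffle-null reference
#'
#' A region is a hub candidate when it sits at or above the 90th percentile
#' of the observed network's node distribution on at least one of degree,
#' strength, or betweenness. A candidate becomes a hub only when a flagged
#' metric also exceeds the 95th percentile of the null distribution of that
#' metric derived from diagonal-preserving shuffles of the correlation
#' matrix (see [null_node_metrics()]). Because the shuffle makes node labels
#' exchangeable, the null distribution is pooled across regions.
#'
#' @param metrics Output of [node_centralities()] on the observed network.
#' @param null_metrics Output of [null_node_metrics()] on the matched null
#'   ensemble, or `NULL` (candidates only, `is_hub` left `NA`).
#' @param percentile Within-network candidate percentile; default 0.90.
#' @param null_percentile Null-exceedance percentile; default 0.95.
#' @return The `metrics` tibble with added columns `is_candidate`, `is_hub`,
#'   and `hub_evidence` (comma-separated metrics that fired both checks).
#' @export
detect_hubs <- function(metrics, null_metrics = NULL, percentile = 0.90,
                        null_percentile = 0.95) {
  mnames <- c("degree", "strength", "betweenness")
  stopifnot(all(c("region", mnames) %in% names(metrics)))
  obs_cut <- vapply(
    mnames, function(m) quantile(metrics[[m]], percentile, names = FALSE),
    numeric(1)
  )
  cand <- sapply(mnames, function(m) metrics[[m]] >= obs_cut[[m]])
  cand <- matrix(cand, nrow = nrow(metrics), dimnames = list(NULL, mnames))
  is_candidate <- rowSums(cand) > 0
  if (is.null(null_metrics)) {
    warn("no null ensemble supplied: hub significance not assessed.")
    return(dplyr::mutate(metrics,
      is_candidate = is_candidate, is_hub = NA,
      hub_evidence = NA_character_
    ))
  }
  null_cut <- vapply(
    mnames, function(m) quantile(null_metrics[[m]], null_percentile, names = FALSE),
    numeric(1)
  )
  fired <- sapply(mnames, function(m) {
    cand[, m] & metrics[[m]] > null_cut[[m]]
  })
  fired <- matrix(fired, nrow = nrow(metrics), dimnames = list(NULL, mnames))
  dplyr::mutate(metrics,
    is_candidate = is_candidate,
    is_hub = rowSums(fired) > 0,
    hub_evidence = apply(fired, 1, function(r) {
      if (!any(r)) NA_character_ else paste(mnames[r], collapse = ",")
    })
  )
}
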