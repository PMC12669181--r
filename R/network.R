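#' Build a signed co-activation network from a correlation matrix
#'
#' Keeps an undirected edge between two regions exactly when the pair's
#' two-tailed p-value is strictly below `alpha`; the edge weight is the
#' signed Spearman rho. Isolated regions stay in the node list. Pairs whose
#' correlation is undefined (a constant region) are excluded both from the
#' edge set and from the count of possible edges.
#'
#' @param cormat A [spearman_matrix()] result (`coact_cormat`).
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @param axis Optional named character vector annotating each region with a
#'   hippocampal axis position (e.g. rostral / medial / caudal-dorsal /
#'   caudal-ventral / parahippocampal).
#' @return An object of class `coact_network`: list with `nodes` (tibble
#'   `region`, optional `axis`), `edges` (tibble `from`, `to`, `rho`, `p`,
#'   upper triangle stored once), `alpha`, `n_possible`, `n_animals`.
#' @examples
#' tab <- simulate_activation_table(factor_spec(n_regions = 8),
#'                                  group_sizes = c(NOR = 7), seed = 1)
#' net <- build_network(spearman_matrix(tab))
#' @export
build_network <- function(cormat, alpha = 0.05, axis = NULL) {
  stopifnot(inherits(cormat, "coact_cormat"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single value in (0, 1].")
  }
  pairs <- tidy.coact_cormat(cormat)
  defined <- !is.na(pairs$rho) & !is.na(pairs$p)
  edges <- pairs[defined & pairs$p < alpha & pairs$rho != 0, , drop = FALSE]
  names(edges) <- c("from", "to", "rho", "p")
  nodes <- tibble::tibble(region = cormat$regions)
  if (!is.null(axis)) {
    nodes$axis <- unname(axis[nodes$region])
  }
  structure(
    list(
      nodes = nodes,
      edges = tibble::as_tibble(edges),
      alpha = alpha,
      n_possible = sum(defined),
      n_animals = cormat$n
    ),
    class = "coact_network"
  )
}

#' @export
print.coact_network <- function(x, ...) {
  comp <- edge_composition(x)
  cat(sprintf(
    "<coact_network> %d regions, %d edges (%d +, %d -) of %d possible, alpha = %g\n",
    nrow(x$nodes), nrow(x$edges), comp$n_pos, comp$n_neg, comp$n_possible,
    x$alpha
  ))
  invisible(x)
}

#' Edge composition of a co-activation network
#'
#' Counts of positive and negative edges and the number of possible region
#' pairs (defined pairs only), the inputs of the between-group chi-square
#' comparison of connection proportions.
#'
#' @param network A `coact_network`.
#' @return A one-row tibble: `n_pos`, `n_neg`, `n_possible`, `proportion`
#'   (edges / possible).
#' @export
edge_composition <- function(network) {
  stopifnot(inherits(network, "coact_network"))
  n_pos <- sum(network$edges$rho > 0)
  n_neg <- sum(network$edges$rho < 0)
  tibble::tibble(
    n_pos = n_pos, n_neg = n_neg, n_possible = network$n_possible,
    proportion = ifelse(network$n_possible > 0,
      (n_pos + n_neg) / network$n_possible, NA_real_
    )
  )
}

#' Convert a co-activation network to an igraph graph
#'
#' Distance-based metrics use edge weights `|rho|` (attribute `weight`) and
#' lengths `1 / |rho|` (attribute `length`); the signed rho is kept as
#' attribute `rho`.
#'
#' @param network A `coact_network`.
#' @return An undirected `igraph` graph with all regions as vertices.
#' @export
as_coact_igraph <- function(network) {
  stopifnot(inherits(network, "coact_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")],
    directed = FALSE,
    vertices = network$nodes$region
  )
  igraph::E(g)$rho <- network$edges$rho
  igraph::E(g)$weight <- abs(network$edges$rho)
  igraph::E(g)$length <- 1 / abs(network$edges$rho)
  g
}

#' @describeIn edge_composition Tidy edge list of the network.
#' @param x A `coact_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.coact_network <- function(x, ...) {
  x$edges
}
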