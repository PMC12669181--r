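# Between-group comparison of network metrics (label-permutation test on
# the animal tables) and of edge proportions (omnibus + pairwise chi-square
# with Bonferroni correction).

#' Permutation comparison of a network metric between two groups
#'
#' The observed statistic is `metric(A) - metric(B)` on networks rebuilt
#' from each group's activation table. The null is obtained by pooling the
#' animals, permuting group labels `B` times (preserving group sizes),
#' rebuilding both networks, and recomputing the difference. The two-tailed
#' p-value uses the permutation-inclusive estimator
#' `(1 + #\{|null| >= |observed|\}) / (B + 1)`, which cannot return zero.
#'
#' @param table_a,table_b Activation tables (one group each, at least 4
#'   animals).
#' @param metric One of `"efficiency"`, `"clustering"`, `"modularity"`,
#'   `"mean_strength"`.
#' @param B Number of label permutations; default 100.
#' @param alpha Edge significance threshold; default 0.05.
#' @param seed Integer seed.
#' @param id_cols Non-region columns.
#' @return A one-row tibble: `metric`, `observed_diff`, `p_value`, `B`,
#'   `n_degenerate` (permutations in which either rebuilt network was
#'   edgeless).
#' @export
bootstrap_compare_metric <- function(table_a, table_b, metric, B = 100L,
                                     alpha = 0.05, seed = 1L,
                                     id_cols = c("animal_id", "group")) {
  B <- as.integer(B)
  if (B < 1L) abort("`B` must be at least 1.")
  f <- network_metric_fun(metric)
  regions <- intersect(region_columns(table_a, id_cols),
                       region_columns(table_b, id_cols))
  if (length(regions) < 2L) abort("tables share fewer than 2 region columns.")
  va <- as.matrix(table_a[, regions, drop = FALSE])
  vb <- as.matrix(table_b[, regions, drop = FALSE])
  if (nrow(va) < 4L || nrow(vb) < 4L) abort("both groups need at least 4 animals.")

  metric_of <- function(mat, seed_i) {
    tab <- tibble::as_tibble(mat)
    tab$animal_id <- sprintf("x%03d", seq_len(nrow(mat)))
    cm <- suppressMessages(spearman_matrix(tab, id_cols = id_cols))
    net <- build_network(cm, alpha = alpha)
    list(value = f(net, seed_i), edgeless = nrow(net$edges) == 0L)
  }

  obs_a <- metric_of(va, derive_seed(seed, "cmp-obs", 1L))
  obs_b <- metric_of(vb, derive_seed(seed, "cmp-obs", 2L))
  observed <- obs_a$value - obs_b$value

  pooled <- rbind(va, vb)
  na <- nrow(va)
  nulls <- with_seed(derive_seed(seed, "cmp-perm"), {
    purrr::map(seq_len(B), function(b) {
      idx <- sample.int(nrow(pooled))
      pa <- metric_of(pooled[idx[seq_len(na)], , drop = FALSE],
                      derive_seed(seed, "cmp-null-a", b))
      pb <- metric_of(pooled[idx[-seq_len(na)], , drop = FALSE],
                      derive_seed(seed, "cmp-null-b", b))
      c(diff = pa$value - pb$value,
        degenerate = as.numeric(pa$edgeless || pb$edgeless))
    })
  })
  nulls <- do.call(rbind, nulls)
  n_degenerate <- sum(nulls[, "degenerate"])
  if (n_degenerate > B / 2) {
    abort(sprintf(
      "degenerate (edgeless) networks in %d of %d permutations: groups too sparse for a %s comparison.",
      n_degenerate, B, metric
    ))
  }
  p_value <- (1 + sum(abs(nulls[, "diff"]) >= abs(observed) - 1e-12)) / (B + 1)
  tibble::tibble(
    metric = metric, observed_diff = observed, p_value = p_value, B = B,
    n_degenerate = as.integer(n_degenerate)
  )
}

#' Chi-square tests of edge proportions between groups
#'
#' Builds a groups x (edge, non-edge) contingency table from each network's
#' edge composition, tests it with an omnibus chi-square, and follows up
#' with pairwise 2x2 chi-squares Bonferroni-corrected over the number of
#' group pairs. When any expected cell falls below 1 a continuity-corrected
#' variant is used for the 2x2 tables and a warning is issued.
#'
#' @param networks Named list of `coact_network` objects (at least 2).
#' @return A list with `omnibus` (tibble `statistic`, `df`, `p.value`),
#'   `pairwise` (tibble `group_a`, `group_b`, `statistic`, `df`, `p_raw`,
#'   `p_corrected`), and `composition` (per-group edge counts and
#'   proportions).
#' @export
edge_count_tests <- function(networks) {
  if (length(networks) < 2L) abort("need at least 2 networks.")
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    abort("`networks` must be a named list (group -> network).")
  }
  comp <- purrr::map_dfr(networks, edge_composition, .id = "group")
  if (any(comp$n_possible == 0)) abort("every network needs n_possible > 0.")
  counts <- cbind(
    edge = comp$n_pos + comp$n_neg,
    non_edge = comp$n_possible - comp$n_pos - comp$n_neg
  )
  rownames(counts) <- comp$group
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  use_cc <- any(expected < 1)
  if (use_cc) {
    warn("expected cell below 1: continuity-corrected 2x2 tests used.")
  }
  omni <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  pairs <- combn(comp$group, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    sub <- counts[pr, , drop = FALSE]
    tst <- suppressWarnings(stats::chisq.test(sub, correct = use_cc))
    tibble::tibble(
      group_a = pr[1], group_b = pr[2],
      statistic = unname(tst$statistic), df = unname(tst$parameter),
      p_raw = tst$p.value
    )
  })
  pairwise$p_corrected <- p.adjust(pairwise$p_raw, method = "bonferroni")
  list(
    omnibus = tibble::tibble(
      statistic = unname(omni$statistic), df = unname(omni$parameter),
      p.value = omni$p.value
    ),
    pairwise = pairwise,
    composition = comp
  )
}
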