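# Centralities, global metrics, Louvain partitions, resolution selection,
# and hub detection, checked against exhaustive enumeration oracles.

test_that("path and star fixtures give textbook centralities", {
  path3 <- make_network(c("a", "b", "c"), tibble::tibble(
    from = c("a", "b"), to = c("b", "c"), rho = c(1, 1)
  ))
  m <- node_centralities(path3)
  expect_equal(m$betweenness[m$region == "b"], 1)
  expect_equal(m$betweenness[m$region != "b"], c(0, 0))
  star <- make_network(c("c0", "l1", "l2", "l3"), tibble::tibble(
    from = rep("c0", 3), to = c("l1", "l2", "l3"), rho = c(1, 1, 1)
  ))
  ms <- node_centralities(star)
  ctr <- ms[ms$region == "c0", ]
  expect_equal(ctr$degree, 3L)
  expect_equal(ctr$strength, 3)
  expect_equal(ctr$betweenness, 3)
})

test_that("centralities match brute-force enumeration on random graphs", {
  for (s in 1:40) {
    net <- random_network(sample(4:8, 1), p_edge = 0.5, seed = s)
    m <- node_centralities(net)
    W <- oracle_adjacency(net)
    expect_equal(m$degree, unname(as.integer(rowSums(W > 0))))
    expect_equal(m$strength, unname(rowSums(W)))
    expect_equal(m$betweenness, unname(oracle_betweenness(net)))
    expect_equal(global_efficiency(net), oracle_efficiency(net))
    expect_equal(
      suppressMessages(global_clustering(net)), oracle_transitivity(net)
    )
  }
})

test_that("global efficiency fixtures and monotonicity hold", {
  k4 <- make_network(sprintf("k%d", 1:4), tibble::tibble(
    from = c("k1", "k1", "k1", "k2", "k2", "k3"),
    to = c("k2", "k3", "k4", "k3", "k4", "k4"), rho = rep(1, 6)
  ))
  expect_equal(global_efficiency(k4), 1)
  path3 <- make_network(c("a", "b", "c"), tibble::tibble(
    from = c("a", "b"), to = c("b", "c"), rho = c(1, 1)
  ))
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)
  empty <- make_network(c("a", "b", "c"), tibble::tibble(
    from = character(), to = character(), rho = numeric()
  ))
  expect_equal(global_efficiency(empty), 0)
  # adding an edge at fixed weights never lowers efficiency
  net <- random_network(7, p_edge = 0.3, seed = 99)
  have <- paste(net$edges$from, net$edges$to)
  all_pairs <- t(combn(net$nodes$region, 2))
  missing <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), ,
                       drop = FALSE]
  base_eff <- global_efficiency(net)
  for (r in seq_len(min(5, nrow(missing)))) {
    net2 <- net
    net2$edges <- dplyr::bind_rows(net2$edges, tibble::tibble(
      from = missing[r, 1], to = missing[r, 2], rho = 0.5, p = 0
    ))
    expect_gte(global_efficiency(net2), base_eff)
  }
})

test_that("clustering fixtures behave", {
  tri <- make_network(c("a", "b", "c"), tibble::tibble(
    from = c("a", "a", "b"), to = c("b", "c", "c"), rho = c(0.5, 0.8, 0.9)
  ))
  expect_equal(global_clustering(tri), 1)
  star <- make_network(c("c0", "l1", "l2", "l3"), tibble::tibble(
    from = rep("c0", 3), to = c("l1", "l2", "l3"), rho = rep(0.7, 3)
  ))
  expect_equal(global_clustering(star), 0)
})

test_that("mean strength satisfies the handshake identity", {
  empty <- make_network(letters[1:3], tibble::tibble(
    from = character(), to = character(), rho = numeric()
  ))
  expect_equal(mean_strength(empty), 0)
  k3 <- make_network(c("a", "b", "c"), tibble::tibble(
    from = c("a", "a", "b"), to = c("b", "c", "c"), rho = rep(1, 3)
  ))
  expect_equal(mean_strength(k3), 2)
  net <- random_network(8, seed = 5)
  expect_equal(
    mean_strength(net), 2 * sum(abs(net$edges$rho)) / nrow(net$nodes)
  )
})

test_that("Louvain separates two disconnected triangles with Q = 0.5", {
  two_tri <- make_network(c(letters[1:3], LETTERS[1:3]), tibble::tibble(
    from = c("a", "a", "b", "A", "A", "B"),
    to = c("b", "c", "c", "B", "C", "C"),
    rho = rep(1, 6)
  ))
  part <- louvain_partition(two_tri, seed = 1)
  expect_equal(part$n_modules, 2)
  expect_equal(part$modularity_q, 0.5)
  a <- tidy(part)
  expect_equal(length(unique(a$module[a$region %in% letters[1:3]])), 1)
  expect_equal(length(unique(a$module[a$region %in% LETTERS[1:3]])), 1)
  # Q equals direct evaluation of the modularity formula
  expect_equal(
    part$modularity_q,
    oracle_modularity(two_tri, setNames(a$module, a$region))
  )
})

test_that("reported Q matches the direct modularity formula on random graphs", {
  for (s in 1:10) {
    net <- random_network(8, p_edge = 0.5, seed = 100 + s)
    if (nrow(net$edges) == 0) next
    part <- louvain_partition(net, seed = s)
    memb <- setNames(part$assignment$module, part$assignment$region)
    expect_equal(part$modularity_q,
                 oracle_modularity(net, memb[net$nodes$region]))
  }
})

test_that("a complete graph collapses to one module", {
  k6 <- make_network(sprintf("v%d", 1:6), {
    pr <- t(combn(1:6, 2))
    tibble::tibble(
      from = sprintf("v%d", pr[, 1]), to = sprintf("v%d", pr[, 2]),
      rho = rep(0.8, nrow(pr))
    )
  })
  mods <- vapply(1:30, function(s) {
    louvain_partition(k6, seed = s)$n_modules
  }, numeric(1))
  expect_gte(mean(mods == 1), 0.99)
})

test_that("planted two-module graphs are recovered", {
  planted_two_module <- function(seed) {
    set.seed(seed)
    regions <- sprintf("v%02d", 1:16)
    pr <- t(combn(1:16, 2))
    within <- (pr[, 1] <= 8) == (pr[, 2] <= 8)
    w <- ifelse(within, 0.9, 0.05)
    make_network(regions, tibble::tibble(
      from = regions[pr[, 1]], to = regions[pr[, 2]], rho = w
    ))
  }
  hits <- vapply(1:50, function(s) {
    part <- louvain_partition(planted_two_module(s), seed = s)
    a <- part$assignment
    part$n_modules == 2 &&
      length(unique(a$module[1:8])) == 1 &&
      length(unique(a$module[9:16])) == 1
  }, logical(1))
  expect_gte(sum(hits), 48)
})

test_that("scaling weights leaves structure metrics unchanged", {
  net <- random_network(8, seed = 77)
  scaled <- net
  scaled$edges$rho <- scaled$edges$rho * 0.5
  m1 <- node_centralities(net)
  m2 <- node_centralities(scaled)
  expect_equal(m1$degree, m2$degree)
  expect_equal(m2$strength, m1$strength * 0.5)
  expect_equal(order(m1$betweenness), order(m2$betweenness))
  expect_equal(
    suppressMessages(global_clustering(net)),
    suppressMessages(global_clustering(scaled))
  )
  p1 <- louvain_partition(net, seed = 3)
  p2 <- louvain_partition(scaled, seed = 3)
  expect_equal(p1$assignment, p2$assignment)
})

test_that("edgeless networks degrade gracefully", {
  empty <- make_network(letters[1:4], tibble::tibble(
    from = character(), to = character(), rho = numeric()
  ))
  expect_warning(part <- louvain_partition(empty), "edgeless")
  expect_equal(part$n_modules, 4)
  expect_equal(part$modularity_q, 0)
  hubs <- detect_hubs(
    node_centralities(empty),
    tibble::tibble(
      member = 1, region = letters[1:4], degree = 0L,
      strength = 0, betweenness = 0
    )
  )
  expect_false(any(hubs$is_hub))
})

test_that("resolution selection is deterministic and honors a single grid", {
  tab <- simulate_activation_table(
    factor_spec(n_regions = 10, n_modules = 2, loading = 0.9),
    c(g = 12), seed = 2
  )
  r1 <- select_resolution(tab, grid = 1, B = 20, seed = 5)
  expect_equal(r1$resolution, 1)
  r2 <- select_resolution(tab, grid = 1, B = 20, seed = 5)
  expect_identical(r1, r2)
  expect_error(select_resolution(tab, grid = numeric()), "non-empty")
  expect_error(select_resolution(tab, grid = 1, B = 5), "at least 10")
})

test_that("resolution selection finds the planted two-module scale", {
  hits <- vapply(1:10, function(s) {
    tab <- simulate_activation_table(
      factor_spec(n_regions = 12, n_modules = 2, loading = 0.95,
                  noise_sd = 0.3),
      c(g = 14), seed = 500 + s
    )
    sel <- select_resolution(tab, grid = c(0.5, 1, 1.3), B = 20,
                             seed = s, alpha = 0.05)
    sel$modal_module_count == 2
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("a planted hub is detected and flagged against the null", {
  planted_hub_cormat <- function(seed) {
    set.seed(seed)
    k <- 16
    regions <- sprintf("r%02d", 1:k)
    pr <- t(combn(1:k, 2))
    # hub r01 connects to everyone; a sparse background elsewhere
    is_hub_edge <- pr[, 1] == 1
    backg <- !is_hub_edge & runif(nrow(pr)) < 0.08
    sig <- pr[is_hub_edge | backg, , drop = FALSE]
    make_cormat(regions, sig, rho = runif(nrow(sig), 0.75, 0.9))
  }
  hits <- vapply(1:8, function(s) {
    cm <- planted_hub_cormat(s)
    net <- build_network(cm)
    ens <- shuffle_null_models(cm, B = 100, seed = s)
    hubs <- detect_hubs(node_centralities(net), null_node_metrics(ens))
    isTRUE(hubs$is_hub[hubs$region == "r01"])
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("homogeneous ring networks produce no spurious hubs", {
  ring_cormat <- function(k) {
    regions <- sprintf("r%02d", 1:k)
    pr <- cbind(1:k, c(2:k, 1))
    pr <- t(apply(pr, 1, sort))
    make_cormat(regions, pr, rho = 0.8)
  }
  cm <- ring_cormat(14)
  net <- build_network(cm)
  false_rates <- vapply(1:8, function(s) {
    ens <- shuffle_null_models(cm, B = 100, seed = 200 + s)
    hubs <- detect_hubs(node_centralities(net), null_node_metrics(ens))
    mean(hubs$is_hub)
  }, numeric(1))
  expect_lte(mean(false_rates), 0.10)
})

test_that("hub detection without a null returns candidates only", {
  net <- random_network(8, seed = 3)
  expect_warning(h <- detect_hubs(node_centralities(net)), "null")
  expect_true(all(is.na(h$is_hub)))
  expect_true(any(h$is_candidate))
})
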