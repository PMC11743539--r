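test_that("closed-form fixtures: complete graph, star, path", {
  k5 <- make_toy_graph("complete", 5)
  expect_equal(clustering_coefficient(k5)$network, 1)
  expect_equal(characteristic_path_length(k5), 1)
  expect_equal(global_efficiency(k5), 1)
  expect_true(all(nodal_efficiency(k5) == 1))
  expect_true(all(nodal_path_length(k5) == 1))
  expect_true(all(betweenness_centrality(k5) == 0))

  s5 <- make_toy_graph("star", 5)
  expect_equal(clustering_coefficient(s5)$network, 0)
  expect_equal(local_efficiency(s5)$network, 0)

  p3 <- make_toy_graph("path", 3)
  expect_equal(characteristic_path_length(p3), 4 / 3, tolerance = 1e-12)
  expect_equal(global_efficiency(p3), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(shortest_path_lengths(p3)),
               matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3))
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))
  expect_equal(unname(nodal_path_length(p3)), c(1.5, 1, 1.5))
})

test_that("degenerate graphs follow the stated conventions", {
  empty <- binary_graph(matrix(0, 4, 4))
  expect_equal(global_efficiency(empty), 0)
  expect_error(characteristic_path_length(empty), "no reachable pair")
  expect_true(all(is.na(nodal_path_length(empty))))
  expect_true(all(nodal_efficiency(empty) == 0))

  # disconnected 2+2: cross-component pairs unreachable
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 1
  d <- shortest_path_lengths(binary_graph(a))
  expect_true(is.na(d[1, 3]))
  expect_equal(d[1, 2], 1)
  # path metrics average reachable pairs; efficiency uses 1/Inf = 0
  expect_equal(characteristic_path_length(binary_graph(a)), 1)
  expect_equal(global_efficiency(binary_graph(a)), 4 / 12)

  tri <- make_toy_graph("complete", 3)
  expect_true(all(clustering_coefficient(tri)$nodal == 1))
  expect_true(all(local_efficiency(tri)$nodal == 1))
})

test_that("every metric matches its brute-force oracle on random graphs", {
  for (seed in 1:10) {
    n <- sample(5:12, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.7), seed = 100 + seed)
    expect_metrics_match_oracle(a)
  }
  # including sparse, likely-disconnected graphs
  for (seed in 1:5) {
    a <- random_adjacency(10, 0.1, seed = 200 + seed)
    expect_metrics_match_oracle(a)
  }
})

test_that("node-mean of nodal efficiency equals global efficiency", {
  for (seed in 1:5) {
    g <- binary_graph(random_adjacency(15, 0.3, seed = seed))
    expect_equal(mean(nodal_efficiency(g)), global_efficiency(g),
                 tolerance = 1e-12)
  }
})

test_that("on connected graphs global efficiency dominates 1/L", {
  found <- 0
  for (seed in 1:10) {
    g <- binary_graph(random_adjacency(12, 0.4, seed = 300 + seed))
    d <- shortest_path_lengths(g)
    if (anyNA(d)) next
    found <- found + 1
    expect_gte(global_efficiency(g, d),
               1 / characteristic_path_length(g, d) - 1e-12)
  }
  expect_gt(found, 0)
})

test_that("adding an edge never decreases efficiency or degree", {
  set.seed(9)
  for (rep in 1:5) {
    a <- random_adjacency(10, 0.3, seed = 400 + rep)
    absent <- which(upper.tri(a) & a == 0, arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[sample.int(nrow(absent), 1), ]
    a2 <- a
    a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- 1
    expect_gte(global_efficiency(binary_graph(a2)),
               global_efficiency(binary_graph(a)) - 1e-12)
    expect_true(all(nodal_degree(binary_graph(a2)) >=
                      nodal_degree(binary_graph(a))))
  }
})

test_that("relabeling nodes permutes all nodal outputs identically", {
  a <- random_adjacency(9, 0.4, seed = 17)
  perm <- sample(9)
  g1 <- binary_graph(a)
  g2 <- binary_graph(a[perm, perm])
  expect_equal(unname(nodal_degree(g2)), unname(nodal_degree(g1))[perm])
  expect_equal(unname(clustering_coefficient(g2)$nodal),
               unname(clustering_coefficient(g1)$nodal)[perm],
               tolerance = 1e-12)
  expect_equal(unname(betweenness_centrality(g2)),
               unname(betweenness_centrality(g1))[perm], tolerance = 1e-12)
  expect_equal(unname(nodal_efficiency(g2)),
               unname(nodal_efficiency(g1))[perm], tolerance = 1e-12)
})

test_that("AUC over sparsity is the trapezoidal integral", {
  s <- seq(0.10, 0.50, 0.01)
  expect_equal(auc_over_sparsity(s, rep(3, 41)), 0.4 * 3, tolerance = 1e-12)
  lin <- (s - 0.10) / 0.40
  expect_equal(auc_over_sparsity(s, lin), 0.2, tolerance = 1e-12)
  set.seed(10)
  v <- rnorm(41)
  expect_equal(auc_over_sparsity(s, v), oracle_trapezoid(s, v),
               tolerance = 1e-12)
  expect_error(auc_over_sparsity(0.1, 1), "at least 2")
  expect_error(auc_over_sparsity(c(0.1, 0.2), c(1, NA)), "at least 2")
})

test_that("sweep_metrics produces one AUC per metric-node curve", {
  z <- distinct_zmatrix(12, seed = 11)
  sw <- build_sweep(z, lo = 0.2, hi = 0.5, step = 0.1)
  sm <- sweep_metrics(sw)
  expect_setequal(unique(sm$curves$sparsity), sw$sparsities)
  glob <- sm$auc[sm$auc$node == "GLOBAL", ]
  expect_setequal(glob$metric, c("clustering", "path_length",
                                 "global_efficiency", "local_efficiency"))
  # AUC recomputable from the stored curves
  cur <- sm$curves[sm$curves$metric == "degree" & sm$curves$node == "R3", ]
  expect_equal(sm$auc$auc[sm$auc$metric == "degree" & sm$auc$node == "R3"],
               oracle_trapezoid(cur$sparsity, cur$value), tolerance = 1e-12)
})
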