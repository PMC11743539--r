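test_that("null realizations conserve node and edge counts in both models", {
  g <- make_toy_graph("watts_strogatz", 50, k = 4, p = 0.1, seed = 1)
  for (model in c("degree_preserving", "erdos_renyi_gnm")) {
    ens <- generate_null(g, model = model, n_realizations = 10L, seed = 2L)
    for (r in ens$realizations) {
      expect_identical(r$n_nodes, g$n_nodes)
      expect_identical(r$n_edges, g$n_edges)
    }
  }
})

test_that("degree-preserving rewiring preserves the exact degree sequence", {
  g <- make_toy_graph("watts_strogatz", 50, k = 4, p = 0.1, seed = 3)
  ens <- generate_null(g, "degree_preserving", n_realizations = 10L, seed = 4L)
  deg <- nodal_degree(g)
  for (r in ens$realizations) {
    expect_identical(unname(nodal_degree(r)), unname(deg))
  }
  # and actually randomizes: at least one realization differs from the source
  changed <- vapply(ens$realizations,
                    function(r) any(r$adjacency != g$adjacency), logical(1))
  expect_true(any(changed))
})

test_that("null ensembles are seed-deterministic", {
  g <- make_toy_graph("erdos_renyi", 30, m = 90, seed = 5)
  for (model in c("degree_preserving", "erdos_renyi_gnm")) {
    e1 <- generate_null(g, model = model, n_realizations = 5L, seed = 7L)
    e2 <- generate_null(g, model = model, n_realizations = 5L, seed = 7L)
    expect_identical(lapply(e1$realizations, `[[`, "adjacency"),
                     lapply(e2$realizations, `[[`, "adjacency"))
  }
})

test_that("unswappable graphs fall back to the source graph with a warning", {
  star <- make_toy_graph("star", 6)
  expect_warning(
    ens <- generate_null(star, "degree_preserving", n_realizations = 3L,
                         seed = 1L),
    "no degree-preserving swap"
  )
  expect_true(all(ens$fallback))
  for (r in ens$realizations) {
    expect_identical(r$adjacency, star$adjacency)
  }
})

test_that("ER nulls of a ring lattice have near-density mean clustering", {
  g <- make_toy_graph("ring_lattice", 60, k = 6)
  ens <- generate_null(g, "erdos_renyi_gnm", n_realizations = 50L, seed = 9L)
  mean_c <- mean(vapply(ens$realizations,
                        function(r) clustering_coefficient(r)$network,
                        numeric(1)))
  density <- 2 * g$n_edges / (g$n_nodes * (g$n_nodes - 1))
  expect_lt(abs(mean_c - density), 0.03)
})

test_that("gamma is identically 1 against a self-null ensemble", {
  g <- make_toy_graph("watts_strogatz", 40, k = 4, p = 0.2, seed = 11)
  self_ens <- structure(
    list(realizations = list(g, g), model = "degree_preserving",
         n_realizations = 2L, seed = 0L, fallback = c(FALSE, FALSE)),
    class = "null_ensemble"
  )
  res <- nodal_swp(g, self_ens)
  finite <- !is.na(res$gamma)
  expect_true(any(finite))
  expect_equal(res$gamma[finite], rep(1, sum(finite)), tolerance = 1e-12)
  expect_equal(res$sigma[finite], rep(1, sum(finite)), tolerance = 1e-12)
})

test_that("the complete graph is its own null: gamma = 1 everywhere", {
  k8 <- make_toy_graph("complete", 8)
  suppressWarnings(
    ens <- generate_null(k8, "degree_preserving", n_realizations = 5L,
                         seed = 1L)
  )
  res <- nodal_swp(k8, ens)
  expect_equal(res$gamma, rep(1, 8), tolerance = 1e-12)
})

test_that("gamma factorizes exactly into the stored ratios", {
  g <- make_toy_graph("erdos_renyi", 25, m = 80, seed = 13)
  ens <- generate_null(g, "degree_preserving", n_realizations = 10L,
                       seed = 14L)
  res <- nodal_swp(g, ens)
  ok <- !is.na(res$gamma)
  expect_equal(res$gamma[ok], (res$c_ratio * res$l_ratio)[ok],
               tolerance = 1e-15)
})

test_that("a ring lattice shows strongly above-random clustering ratios", {
  g <- make_toy_graph("ring_lattice", 100, k = 6)
  # closed-form lattice clustering: C = 3(k-2) / (4(k-1)) for ring lattices
  c_lattice <- clustering_coefficient(g)$network
  expect_equal(c_lattice, 3 * (6 - 2) / (4 * (6 - 1)), tolerance = 1e-12)
  ens <- generate_null(g, "erdos_renyi_gnm", n_realizations = 30L, seed = 15L)
  res <- nodal_swp(g, ens)
  expect_gt(median(res$c_ratio, na.rm = TRUE), 3)
})

test_that("sweep_swp emits curves and AUCs per node", {
  z <- distinct_zmatrix(15, seed = 16)
  sw <- build_sweep(z, lo = 0.2, hi = 0.4, step = 0.1)
  res <- sweep_swp(sw, n_realizations = 5L, seed = 17L)
  expect_setequal(unique(res$curves$sparsity), sw$sparsities)
  expect_equal(nrow(res$auc), 2 * 15)
  got <- res$auc$auc[res$auc$metric == "gamma" & res$auc$node == "R2"]
  cur <- res$curves[res$curves$node == "R2", ]
  expect_equal(got, oracle_trapezoid(cur$sparsity, cur$gamma),
               tolerance = 1e-12)
})
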