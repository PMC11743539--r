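# Independent brute-force oracles for graph metrics, written directly from
# the definitions (BFS by hand, triangle enumeration, shortest-path counting
# by dynamic programming). Deliberately free of igraph and of the package's
# own metric code.

oracle_bfs <- function(a, source) {
  n <- nrow(a)
  dist <- rep(NA_real_, n)
  dist[source] <- 0
  frontier <- source
  level <- 0
  while (length(frontier)) {
    level <- level + 1
    nxt <- integer()
    for (v in frontier) {
      for (u in which(a[v, ] == 1)) {
        if (is.na(dist[u])) {
          dist[u] <- level
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(NA_real_, n, n)
  for (s in seq_len(n)) d[s, ] <- oracle_bfs(a, s)
  d
}

oracle_degree <- function(a) rowSums(a)

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in seq_len(k - 1)) {
      for (y in (x + 1):k) {
        if (a[nb[x], nb[y]] == 1) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

oracle_char_path <- function(a) {
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  mean(off[!is.na(off)])
}

oracle_global_eff <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- oracle_distances(a)
  inv <- 1 / d
  inv[is.na(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_eff <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_eff(a[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_nodal_path <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[!is.na(di)]
    if (!length(di)) NA_real_ else mean(di)
  }, numeric(1))
}

oracle_nodal_eff <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  inv <- 1 / d
  inv[is.na(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

# Shortest-path counts by layer DP: nsp[s, t] = number of geodesics s -> t.
oracle_path_counts <- function(a, d) {
  n <- nrow(a)
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    nsp[s, s] <- 1
    reach <- which(!is.na(d[s, ]) & d[s, ] > 0)
    for (t in reach[order(d[s, reach])]) {
      preds <- which(a[, t] == 1 & !is.na(d[s, ]) & d[s, ] == d[s, t] - 1)
      nsp[s, t] <- sum(nsp[s, preds])
    }
  }
  nsp
}

# Unnormalized betweenness: sum over unordered pairs (s, t), s != v != t,
# of the fraction of s-t geodesics passing through v.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  nsp <- oracle_path_counts(a, d)
  b <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      if (is.na(d[s, t]) || nsp[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (!is.na(d[s, v]) && !is.na(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          b[v] <- b[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
        }
      }
    }
  }
  b
}

oracle_trapezoid <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# random adjacency matrix, edge probability p
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# all labeled graphs on n nodes (2^(n(n-1)/2) of them), as adjacency matrices
all_labeled_graphs <- function(n) {
  n_pairs <- n * (n - 1) / 2
  lapply(0:(2^n_pairs - 1), function(code) {
    bits <- as.numeric(intToBits(code)[seq_len(n_pairs)])
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- bits
    a + t(a)
  })
}

# compare every package metric against its oracle on one adjacency matrix
expect_metrics_match_oracle <- function(a, tol = 1e-12) {
  g <- binary_graph(a)
  d <- shortest_path_lengths(g)
  expect_equal(unname(nodal_degree(g)), oracle_degree(a), tolerance = tol)
  expect_equal(unname(clustering_coefficient(g)$nodal), oracle_clustering(a),
               tolerance = tol)
  expect_equal(unname(d), oracle_distances(a), tolerance = tol)
  if (any(!is.na(oracle_distances(a)[upper.tri(a)]))) {
    expect_equal(characteristic_path_length(g, d), oracle_char_path(a),
                 tolerance = tol)
  }
  expect_equal(global_efficiency(g, d), oracle_global_eff(a), tolerance = tol)
  expect_equal(unname(local_efficiency(g)$nodal), oracle_local_eff(a),
               tolerance = tol)
  expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(a),
               tolerance = tol)
  expect_equal(unname(nodal_path_length(g, d)), oracle_nodal_path(a),
               tolerance = tol)
  expect_equal(unname(nodal_efficiency(g, d)), oracle_nodal_eff(a),
               tolerance = tol)
}
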