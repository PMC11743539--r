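#' Nodal degree
#'
#' Number of edges incident to each node, \eqn{k_i = \sum_j A_{ij}}.
#'
#' @param g a [binary_graph()].
#' @return Named integer vector, one value per node.
#' @export
nodal_degree <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- rowSums(g$adjacency)
  storage.mode(d) <- "integer"
  d
}

#' Clustering coefficient
#'
#' Per-node triangle density \eqn{2T_i / (k_i(k_i-1))}: the fraction of a
#' node's neighbor pairs that are themselves connected. Nodes with fewer
#' than two neighbors have no neighbor pairs and score 0; the network value
#' is the mean over all `N` nodes (including those zeros).
#'
#' @param g a [binary_graph()].
#' @return List with `nodal` (values in \[0, 1\]) and `network` (their mean).
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  cc <- igraph::transitivity(as_igraph(g), type = "local", isolates = "zero")
  names(cc) <- rownames(g$adjacency)
  list(nodal = cc, network = mean(cc))
}

#' All-pairs shortest path lengths
#'
#' Breadth-first-search distances on the binary graph. Unreachable pairs are
#' `NA`; the diagonal is 0.
#'
#' @param g a [binary_graph()].
#' @return Symmetric numeric matrix of hop counts with `NA` for unreachable
#'   pairs.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- igraph::distances(as_igraph(g))
  d[is.infinite(d)] <- NA_real_
  dimnames(d) <- dimnames(g$adjacency)
  d
}

#' Characteristic path length
#'
#' Mean shortest path length over all ordered pairs \eqn{i \ne j}. On
#' disconnected graphs the mean is taken over reachable pairs only.
#'
#' @param g a [binary_graph()].
#' @param d optional precomputed distance matrix from
#'   [shortest_path_lengths()].
#' @return Scalar path length; errors if no pair is reachable.
#' @export
characteristic_path_length <- function(g, d = shortest_path_lengths(g)) {
  off <- d[row(d) != col(d)]
  off <- off[!is.na(off)]
  if (!length(off)) stop("undefined path length: graph has no reachable pair")
  mean(off)
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all ordered pairs,
#' \eqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}}, with
#' unreachable pairs contributing 0 (the \eqn{1/\infty} convention). Equals
#' 1 on a complete graph and 0 on an edgeless one.
#'
#' @inheritParams characteristic_path_length
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(g, d = shortest_path_lengths(g)) {
  n <- nrow(d)
  if (n < 2L) return(0)
  inv <- 1 / d
  inv[is.na(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors (the node itself excluded); nodes with fewer than two
#' neighbors score 0. The network value is the mean over all `N` nodes.
#'
#' @param g a [binary_graph()].
#' @return List with `nodal` and `network` (mean over nodes).
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  a <- g$adjacency
  n <- g$n_nodes
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2L) return(0)
    sub <- binary_graph(a[nb, nb, drop = FALSE])
    global_efficiency(sub)
  }, numeric(1))
  names(vals) <- rownames(a)
  list(nodal = vals, network = mean(vals))
}

#' Betweenness centrality
#'
#' Standard shortest-path betweenness with fractional credit across
#' equal-length paths, unnormalized (each unordered pair counted once).
#'
#' @param g a [binary_graph()].
#' @param normalized divide by `(N-1)(N-2)/2` if `TRUE`.
#' @return Named numeric vector per node.
#' @export
betweenness_centrality <- function(g, normalized = FALSE) {
  stopifnot(inherits(g, "binary_graph"))
  b <- igraph::betweenness(as_igraph(g), directed = FALSE,
                           normalized = normalized)
  names(b) <- rownames(g$adjacency)
  b
}

#' Nodal path length
#'
#' Mean shortest path length from each node to the nodes it can reach.
#' An isolated node (or one in a singleton component) has no reachable
#' partner and is marked `NA`.
#'
#' @inheritParams characteristic_path_length
#' @return Named numeric vector per node, `NA` where undefined.
#' @export
nodal_path_length <- function(g, d = shortest_path_lengths(g)) {
  n <- nrow(d)
  vals <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[!is.na(di)]
    if (!length(di)) NA_real_ else mean(di)
  }, numeric(1))
  names(vals) <- rownames(d)
  vals
}

#' Nodal efficiency
#'
#' Mean inverse distance from each node to all others,
#' \eqn{\frac{1}{N-1}\sum_{j \ne i} 1/d_{ij}}, unreachable pairs
#' contributing 0. The mean over nodes equals the global efficiency.
#'
#' @inheritParams characteristic_path_length
#' @return Named numeric vector per node in \[0, 1\].
#' @export
nodal_efficiency <- function(g, d = shortest_path_lengths(g)) {
  n <- nrow(d)
  inv <- 1 / d
  inv[is.na(inv)] <- 0
  diag(inv) <- 0
  vals <- rowSums(inv) / (n - 1)
  names(vals) <- rownames(d)
  vals
}

#' All global and nodal metrics for one graph
#'
#' Computes every metric of the pipeline on one binary graph and returns a
#' long-format table.
#'
#' @param g a [binary_graph()].
#' @return data.frame with columns `metric`, `node` (`"GLOBAL"` for
#'   network-level values), `value`.
#' @export
graph_metrics <- function(g) {
  d <- shortest_path_lengths(g)
  cc <- clustering_coefficient(g)
  le <- local_efficiency(g)
  deg <- nodal_degree(g)
  bet <- betweenness_centrality(g)
  npl <- nodal_path_length(g, d)
  neff <- nodal_efficiency(g, d)
  L <- tryCatch(characteristic_path_length(g, d), error = function(e) NA_real_)
  nodes <- rownames(g$adjacency)
  glob <- data.frame(
    metric = c("clustering", "path_length", "global_efficiency",
               "local_efficiency"),
    node = "GLOBAL",
    value = c(cc$network, L, global_efficiency(g, d), le$network),
    stringsAsFactors = FALSE
  )
  nod <- data.frame(
    metric = rep(c("degree", "clustering", "local_efficiency", "betweenness",
                   "nodal_path", "nodal_efficiency"), each = length(nodes)),
    node = rep(nodes, times = 6L),
    value = c(deg, cc$nodal, le$nodal, bet, npl, neff),
    stringsAsFactors = FALSE
  )
  rbind(glob, nod)
}

#' Trapezoidal area under a metric's sparsity curve
#'
#' Summarizes a metric's values across the sparsity sweep by the trapezoidal
#' integral over the sparsity axis, the threshold-free quantity used for all
#' group statistics. Points with undefined values (`NA`) are dropped
#' pairwise before integration.
#'
#' @param sparsities strictly increasing sparsity grid.
#' @param values metric values on the grid.
#' @return Scalar area (metric units times sparsity width).
#' @export
#' @examples
#' auc_over_sparsity(seq(0.1, 0.5, 0.01), rep(2, 41))  # 0.8
auc_over_sparsity <- function(sparsities, values) {
  stopifnot(length(sparsities) == length(values))
  ok <- !is.na(values)
  s <- sparsities[ok]
  v <- values[ok]
  if (length(s) < 2L) stop("AUC needs at least 2 finite curve points")
  if (any(diff(s) <= 0)) stop("sparsities must be strictly increasing")
  sum(diff(s) * (v[-1] + v[-length(v)]) / 2)
}

#' Metric curves and AUCs across a sparsity sweep
#'
#' Runs [graph_metrics()] on every graph of a sweep and summarizes each
#' (metric, node) curve by its AUC.
#'
#' @param sweep a [build_sweep()] result.
#' @return List with `curves` (long data.frame: `sparsity`, `metric`,
#'   `node`, `value`) and `auc` (data.frame: `metric`, `node`, `auc`).
#' @export
sweep_metrics <- function(sweep) {
  stopifnot(inherits(sweep, "sparsity_sweep"))
  tabs <- Map(function(g, s) {
    tab <- graph_metrics(g)
    tab$sparsity <- s
    tab
  }, sweep$graphs, sweep$sparsities)
  curves <- do.call(rbind, tabs)
  curves <- curves[, c("sparsity", "metric", "node", "value")]
  key <- interaction(curves$metric, curves$node, drop = TRUE, sep = "\r")
  auc <- do.call(rbind, lapply(split(curves, key), function(df) {
    a <- tryCatch(auc_over_sparsity(df$sparsity, df$value),
                  error = function(e) NA_real_)
    data.frame(metric = df$metric[1L], node = df$node[1L], auc = a,
               stringsAsFactors = FALSE)
  }))
  rownames(auc) <- NULL
  list(curves = curves, auc = auc)
}
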