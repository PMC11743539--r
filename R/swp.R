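#' Random-network null ensemble for a binary graph
#'
#' Generates reference random networks with the same number of nodes and
#' edges as the source graph. `"degree_preserving"` additionally preserves
#' the exact degree sequence via Maslov-Sneppen double-edge swaps
#' (`swap_factor * n_edges` attempted swaps per realization, proposals
#' creating self-loops or multi-edges rejected). `"erdos_renyi_gnm"` draws
#' uniformly among graphs with the same node and edge counts.
#'
#' Graphs admitting no valid swap (e.g. a star) cannot be randomized while
#' preserving degrees; realizations then equal the source graph and a
#' warning is raised, with the fallback recorded in the result.
#'
#' @param g a [binary_graph()].
#' @param model `"degree_preserving"` or `"erdos_renyi_gnm"`.
#' @param n_realizations ensemble size.
#' @param seed RNG seed (ensemble is fully seed-deterministic).
#' @param swap_factor attempted swaps per edge for the rewiring model.
#' @return A `null_ensemble` list: `realizations` (list of
#'   [binary_graph()]), `model`, `n_realizations`, `seed`, `fallback`
#'   (logical per realization: TRUE where no swap succeeded).
#' @export
generate_null <- function(g, model = c("degree_preserving", "erdos_renyi_gnm"),
                          n_realizations = 100L, seed = 1L, swap_factor = 10L) {
  model <- match.arg(model)
  stopifnot(inherits(g, "binary_graph"), n_realizations >= 1L)
  set.seed(seed)
  n <- g$n_nodes
  fallback <- logical(n_realizations)
  realizations <- vector("list", n_realizations)
  if (model == "erdos_renyi_gnm") {
    n_pairs <- n * (n - 1L) / 2
    pairs <- which(upper.tri(g$adjacency), arr.ind = TRUE)
    for (r in seq_len(n_realizations)) {
      a <- matrix(0, n, n)
      pick <- sample.int(n_pairs, g$n_edges)
      a[pairs[pick, , drop = FALSE]] <- 1
      a <- a + t(a)
      dimnames(a) <- dimnames(g$adjacency)
      realizations[[r]] <- binary_graph(a, sparsity = g$sparsity)
    }
  } else {
    edges <- which(upper.tri(g$adjacency) & g$adjacency == 1, arr.ind = TRUE)
    if (nrow(edges) < 2L) {
      stop("degree-preserving rewiring needs at least 2 edges")
    }
    n_attempts <- as.integer(swap_factor) * nrow(edges)
    for (r in seq_len(n_realizations)) {
      res <- double_edge_swap(g$adjacency, edges, n_attempts)
      if (res$n_success == 0L) fallback[r] <- TRUE
      realizations[[r]] <- binary_graph(res$adjacency, sparsity = g$sparsity)
    }
    if (any(fallback)) {
      warning(sprintf(paste0("graph admits no degree-preserving swap in ",
                             "%d of %d realizations; those equal the source ",
                             "graph"), sum(fallback), n_realizations))
    }
  }
  structure(
    list(realizations = realizations, model = model,
         n_realizations = as.integer(n_realizations), seed = as.integer(seed),
         fallback = fallback),
    class = "null_ensemble"
  )
}

# Maslov-Sneppen double-edge swaps on an adjacency matrix.
# Picks two distinct edges (a,b),(c,d) and proposes (a,d),(c,b); accepted
# only if no self-loop or multi-edge would result. Preserves every degree.
double_edge_swap <- function(a, edges, n_attempts) {
  m <- nrow(edges)
  n_success <- 0L
  for (it in seq_len(n_attempts)) {
    e <- sample.int(m, 2L)
    p <- edges[e[1L], ]; q <- edges[e[2L], ]
    # random orientation of the second edge
    if (stats::runif(1) < 0.5) q <- rev(q)
    a1 <- p[1L]; b1 <- p[2L]; c1 <- q[1L]; d1 <- q[2L]
    if (a1 == c1 || a1 == d1 || b1 == c1 || b1 == d1) next
    if (a[a1, d1] == 1 || a[c1, b1] == 1) next
    a[a1, b1] <- 0; a[b1, a1] <- 0
    a[c1, d1] <- 0; a[d1, c1] <- 0
    a[a1, d1] <- 1; a[d1, a1] <- 1
    a[c1, b1] <- 1; a[b1, c1] <- 1
    edges[e[1L], ] <- sort(c(a1, d1))
    edges[e[2L], ] <- sort(c(c1, b1))
    n_success <- n_success + 1L
  }
  list(adjacency = a, n_success = n_success)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %d %s realizations (seed %d)\n",
              x$n_realizations, x$model, x$seed))
  invisible(x)
}

#' Nodal small-world propensity against a random-network null
#'
#' For each node i, compares its observed clustering coefficient and nodal
#' path length with the ensemble means of the same quantities over the
#' random realizations, and combines the two ratios multiplicatively:
#'
#' \deqn{\gamma_i = \frac{C_i^{obs}}{C_i^{rand}} \times
#'   \frac{L_i^{obs}}{L_i^{rand}}}
#'
#' A node scores high when both its clustering and its path length exceed
#' the random reference. The classical small-worldness ratio
#' \eqn{\sigma_i = (C_i^{obs}/C_i^{rand}) / (L_i^{obs}/L_i^{rand})}, which
#' instead rewards shorter-than-random paths, is reported alongside under
#' its own column; the two indices answer different questions and are never
#' mixed. Ratios are `NA` where a null mean is 0 or a nodal path length is
#' undefined.
#'
#' @param g the observed [binary_graph()].
#' @param ensemble a [generate_null()] ensemble built from `g`.
#' @return data.frame per node: `node`, `c_observed`, `c_random`,
#'   `l_observed`, `l_random`, `c_ratio`, `l_ratio`, `gamma` (product form),
#'   `sigma` (classical quotient form).
#' @export
nodal_swp <- function(g, ensemble) {
  stopifnot(inherits(g, "binary_graph"), inherits(ensemble, "null_ensemble"))
  if (!length(ensemble$realizations)) stop("empty null ensemble")
  same_size <- vapply(ensemble$realizations, function(r) {
    r$n_nodes == g$n_nodes && r$n_edges == g$n_edges
  }, logical(1))
  if (!all(same_size)) stop("ensemble was not generated from this graph")
  c_obs <- clustering_coefficient(g)$nodal
  l_obs <- nodal_path_length(g)
  null_c <- vapply(ensemble$realizations,
                   function(r) clustering_coefficient(r)$nodal,
                   numeric(g$n_nodes))
  null_l <- vapply(ensemble$realizations,
                   function(r) nodal_path_length(r),
                   numeric(g$n_nodes))
  null_c <- matrix(null_c, nrow = g$n_nodes)
  null_l <- matrix(null_l, nrow = g$n_nodes)
  c_rand <- rowMeans(null_c)
  l_rand <- rowMeans(null_l)          # NA if any realization leaves i isolated
  c_ratio <- ifelse(c_rand > 0, c_obs / c_rand, NA_real_)
  l_ratio <- ifelse(!is.na(l_rand) & l_rand > 0 & !is.na(l_obs),
                    l_obs / l_rand, NA_real_)
  data.frame(
    node = rownames(g$adjacency),
    c_observed = c_obs, c_random = c_rand,
    l_observed = l_obs, l_random = l_rand,
    c_ratio = c_ratio, l_ratio = l_ratio,
    gamma = c_ratio * l_ratio,
    sigma = c_ratio / l_ratio,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Small-world propensity across a sparsity sweep
#'
#' Runs [generate_null()] + [nodal_swp()] at every sparsity of a sweep and
#' summarizes each node's gamma and sigma curves by their AUC.
#'
#' @param sweep a [build_sweep()] result.
#' @param model,n_realizations,swap_factor passed to [generate_null()].
#' @param seed master seed; each sparsity level gets its own child seed.
#' @return List with `curves` (long data.frame: `sparsity`, `node`,
#'   `c_ratio`, `l_ratio`, `gamma`, `sigma`) and `auc` (data.frame:
#'   `metric` in gamma/sigma, `node`, `auc`).
#' @export
sweep_swp <- function(sweep, model = c("degree_preserving", "erdos_renyi_gnm"),
                      n_realizations = 100L, seed = 1L, swap_factor = 10L) {
  model <- match.arg(model)
  stopifnot(inherits(sweep, "sparsity_sweep"))
  tabs <- Map(function(g, s, i) {
    ens <- generate_null(g, model = model, n_realizations = n_realizations,
                         seed = child_seed(seed, paste0("swp_null_", i)),
                         swap_factor = swap_factor)
    tab <- nodal_swp(g, ens)
    tab$sparsity <- s
    tab
  }, sweep$graphs, sweep$sparsities, seq_along(sweep$graphs))
  curves <- do.call(rbind, tabs)
  curves <- curves[, c("sparsity", "node", "c_ratio", "l_ratio",
                       "gamma", "sigma")]
  auc <- do.call(rbind, lapply(c("gamma", "sigma"), function(metric) {
    do.call(rbind, lapply(split(curves, curves$node), function(df) {
      a <- tryCatch(auc_over_sparsity(df$sparsity, df[[metric]]),
                    error = function(e) NA_real_)
      data.frame(metric = metric, node = df$node[1L], auc = a,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(auc) <- NULL
  list(curves = curves, auc = auc)
}
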