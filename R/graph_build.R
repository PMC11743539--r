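#' Construct a binary graph object
#'
#' Undirected, unweighted graph stored as a symmetric 0/1 adjacency matrix
#' with zero diagonal: the substrate for all graph metrics.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param sparsity fraction of possible edges present (computed if `NULL`).
#' @return A `binary_graph` list with `adjacency`, `n_nodes`, `n_edges`,
#'   `sparsity`.
#' @export
binary_graph <- function(adjacency, sparsity = NULL) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be 0/1")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  n <- nrow(adjacency)
  m <- sum(adjacency) / 2
  if (is.null(rownames(adjacency))) {
    dimnames(adjacency) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
  }
  if (is.null(sparsity)) sparsity <- if (n > 1) m / (n * (n - 1) / 2) else 0
  structure(
    list(adjacency = adjacency, n_nodes = n, n_edges = as.integer(m),
         sparsity = sparsity),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges (sparsity %.3f)\n",
              x$n_nodes, x$n_edges, x$sparsity))
  invisible(x)
}

#' @keywords internal
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

# round-half-away-from-zero so sparsity -> edge count is a fixed pure function
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Proportional threshold: binarize a connectivity matrix at a sparsity
#'
#' Retains exactly `k = round(sparsity * N(N-1)/2)` strongest off-diagonal
#' pairs as edges, so every subject's graph has the same density regardless
#' of their overall connectivity strength. In `"signed"` mode edges are
#' ranked by raw z, so the strongest positive couplings are kept; in
#' `"absolute"` mode by |z|. Exact ties at the cutoff are resolved
#' deterministically in lexicographic (i, j) order, i < j.
#'
#' @param z a [zmatrix()] (or bare symmetric matrix).
#' @param sparsity fraction of possible edges to retain, in (0, 1\].
#' @param mode `"signed"` or `"absolute"` ranking.
#' @return A [binary_graph()] with exactly `k` edges.
#' @export
#' @examples
#' z <- matrix(0, 5, 5); z[upper.tri(z)] <- seq(0.1, 1, length.out = 10)
#' z <- z + t(z)
#' proportional_threshold(zmatrix(z), 0.2)$n_edges  # 2
proportional_threshold <- function(z, sparsity,
                                   mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  zm <- if (inherits(z, "zmatrix")) z$z else z
  stopifnot(is.matrix(zm), nrow(zm) == ncol(zm))
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must lie in (0, 1]")
  n <- nrow(zm)
  n_pairs <- n * (n - 1) / 2
  k <- as.integer(round_half_away(sparsity * n_pairs))
  if (k == 0L) {
    stop(sprintf("empty graph requested: sparsity %.4f rounds to 0 of %d edges",
                 sparsity, n_pairs))
  }
  ut <- which(upper.tri(zm), arr.ind = TRUE)   # lexicographic in (j, i); reorder
  ord_pairs <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord_pairs, , drop = FALSE]
  w <- zm[ut]
  if (mode == "absolute") w <- abs(w)
  # descending weight, ties broken by (i, j) lexicographic order
  keep <- order(-w, seq_along(w))[seq_len(k)]
  a <- matrix(0, n, n)
  a[ut[keep, , drop = FALSE]] <- 1
  a <- a + t(a)
  dimnames(a) <- dimnames(zm)
  binary_graph(a, sparsity = sparsity)
}

#' Build the full sparsity sweep for one connectome
#'
#' Thresholds a z matrix at every sparsity in `{lo, lo+step, ..., hi}`
#' (endpoint inclusive within 1e-9). With the default 0.10--0.50 range in
#' 0.01 steps this yields 41 graphs. When all weights are distinct the edge
#' sets are nested: each graph's edges are a superset of every sparser
#' graph's.
#'
#' @param z a [zmatrix()].
#' @param lo,hi,step sweep bounds and increment.
#' @param mode ranking mode, as in [proportional_threshold()].
#' @return A `sparsity_sweep` list with `graphs` (list of [binary_graph()])
#'   and `sparsities`.
#' @export
build_sweep <- function(z, lo = 0.10, hi = 0.50, step = 0.01,
                        mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(lo <= hi, step > 0)
  n_steps <- floor((hi - lo) / step + 1e-9)
  sparsities <- lo + step * (0:n_steps)
  graphs <- lapply(sparsities, function(s) proportional_threshold(z, s, mode))
  structure(list(graphs = graphs, sparsities = sparsities),
            class = "sparsity_sweep")
}

#' @export
print.sparsity_sweep <- function(x, ...) {
  cat(sprintf("Sparsity sweep: %d graphs, sparsity %.2f to %.2f\n",
              length(x$graphs), min(x$sparsities), max(x$sparsities)))
  invisible(x)
}
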