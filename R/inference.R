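#' Build a design matrix for group inference
#'
#' Columns: intercept, group indicator (second factor level = 1), and the
#' nuisance covariates age and mean framewise displacement.
#'
#' @param covariates data.frame with `subject_id`, `group`, `age`,
#'   `mean_fd` (see [read_covariates()]).
#' @param use_covariates include age and mean FD as nuisance columns.
#' @return Numeric matrix with attributes `group_col` (column index of the
#'   group indicator) and `subject_id`.
#' @export
design_matrix <- function(covariates, use_covariates = TRUE) {
  covariates <- validate_covariates(covariates)
  grp <- as.integer(covariates$group == levels(covariates$group)[2L])
  if (use_covariates) {
    x <- cbind(intercept = 1, group = grp, age = covariates$age,
               mean_fd = covariates$mean_fd)
  } else {
    x <- cbind(intercept = 1, group = grp)
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[-qrx$pivot[seq_len(qrx$rank)]]
    stop("rank-deficient design: collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  attr(x, "group_col") <- 2L
  attr(x, "subject_id") <- covariates$subject_id
  x
}

# Stack each subject's upper-triangular z values into a subjects x edges
# matrix; returns the matrix plus the (i, j) index of every edge column.
#' Stack z matrices into an edge-by-subject response matrix
#'
#' @param z_matrices list of [zmatrix()] objects with identical regions.
#' @return List with `values` (subjects x edges matrix), `edges`
#'   (data.frame `i`, `j`, `region_i`, `region_j`), `subject_id`.
#' @export
edge_matrix <- function(z_matrices) {
  stopifnot(length(z_matrices) >= 1L)
  z1 <- z_matrices[[1L]]$z
  n <- nrow(z1)
  ut <- which(upper.tri(z1), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  vals <- t(vapply(z_matrices, function(zm) zm$z[ut], numeric(nrow(ut))))
  labs <- z_matrices[[1L]]$region_names
  list(
    values = vals,
    edges = data.frame(i = ut[, 1L], j = ut[, 2L],
                       region_i = labs[ut[, 1L]], region_j = labs[ut[, 2L]],
                       stringsAsFactors = FALSE),
    subject_id = vapply(z_matrices, `[[`, character(1), "subject_id")
  )
}

# Vectorized OLS t statistics for one coefficient across many responses.
# x: n x p design; y: n x m responses. Returns list(beta, t).
ols_t <- function(x, y, coef_col) {
  n <- nrow(x); p <- ncol(x)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  beta <- xtx_inv %*% crossprod(x, y)           # p x m
  res <- y - x %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(sigma2 * xtx_inv[coef_col, coef_col])
  tval <- beta[coef_col, ] / se
  tval[se == 0] <- 0
  list(beta = beta[coef_col, ], t = tval, df = n - p)
}

#' Edgewise group GLM
#'
#' Fits, for every edge, an ordinary least-squares model of the Fisher-z
#' connectivity on the design (intercept, group, and any nuisance
#' covariates) and returns the group coefficient's t statistic and effect
#' estimate. With no covariates this reduces exactly to the pooled-variance
#' two-sample t test.
#'
#' @param z_matrices list of [zmatrix()] objects, or an [edge_matrix()].
#' @param design matrix from [design_matrix()].
#' @return data.frame per edge: `i`, `j`, `region_i`, `region_j`,
#'   `effect` (group coefficient), `t`; attribute `df`.
#' @export
edgewise_glm <- function(z_matrices, design) {
  em <- if (is.list(z_matrices) && !is.null(z_matrices$values)) z_matrices
        else edge_matrix(z_matrices)
  if (nrow(em$values) != nrow(design)) {
    stop("subjects misaligned: ", nrow(em$values), " matrices vs ",
         nrow(design), " design rows")
  }
  fit <- ols_t(design, em$values, attr(design, "group_col"))
  out <- em$edges
  out$effect <- fit$beta
  out$t <- fit$t
  attr(out, "df") <- fit$df
  out
}

# Draw n_perm permutations of seq_len(n), as an n_perm x n index matrix.
# The same shuffles are reused across all edges so the joint null
# dependence between edges is preserved.
permutation_indices <- function(n, n_perm, seed) {
  set.seed(seed)
  t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
}

# Freedman-Lane permutation t statistics: residualize the responses under
# the reduced model (design without the group column), permute those
# residuals, add back the reduced fit, and recompute the full-model group t.
# Returns an n_perm x m matrix of t statistics.
freedman_lane_t <- function(x, y, group_col, perms) {
  z <- x[, -group_col, drop = FALSE]
  hz <- z %*% chol2inv(chol(crossprod(z))) %*% t(z)
  fitted_red <- hz %*% y
  resid_red <- y - fitted_red
  n_perm <- nrow(perms)
  out <- matrix(0, n_perm, ncol(y))
  for (b in seq_len(n_perm)) {
    y_star <- fitted_red + resid_red[perms[b, ], , drop = FALSE]
    out[b, ] <- ols_t(x, y_star, group_col)$t
  }
  out
}

#' Edgewise permutation test with BH-FDR correction
#'
#' Permutation p-value per edge from group-label shuffles (Freedman-Lane
#' residual permutation when nuisance covariates are present; the same
#' shuffles are reused across edges), with Benjamini-Hochberg adjustment
#' across the edge family. The p estimator is
#' \eqn{(1 + \#\{|t^*| \ge |t|\}) / (1 + n_{perm})}.
#'
#' @param z_matrices list of [zmatrix()] objects or an [edge_matrix()].
#' @param design matrix from [design_matrix()].
#' @param n_perm number of permutations.
#' @param seed RNG seed for the shuffles.
#' @param q FDR level for the decision column.
#' @return data.frame per edge: indices/labels, `effect`, `t`, `p_perm`,
#'   `p_fdr`, `significant`.
#' @export
edgewise_fdr <- function(z_matrices, design, n_perm = 1000L, seed = 1L,
                         q = 0.05) {
  em <- if (is.list(z_matrices) && !is.null(z_matrices$values)) z_matrices
        else edge_matrix(z_matrices)
  obs <- edgewise_glm(em, design)
  perms <- permutation_indices(nrow(design), n_perm, seed)
  t_null <- freedman_lane_t(design, em$values, attr(design, "group_col"),
                            perms)
  exceed <- colSums(abs(t_null) >= matrix(abs(obs$t), n_perm, ncol(t_null),
                                          byrow = TRUE))
  obs$p_perm <- (1 + exceed) / (1 + n_perm)
  obs$p_fdr <- stats::p.adjust(obs$p_perm, method = "BH")
  obs$significant <- obs$p_fdr <= q
  obs
}

# Decompose suprathreshold edges into connected components; returns a list
# of components (edge-index vectors) ordered by decreasing edge count.
edge_components <- function(edges_df, supra) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  verts <- unique(c(edges_df$i[idx], edges_df$j[idx]))
  g <- igraph::graph_from_edgelist(
    cbind(match(edges_df$i[idx], verts), match(edges_df$j[idx], verts)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  edge_comp <- comp[match(edges_df$i[idx], verts)]
  comps <- split(idx, edge_comp)
  comps[order(-lengths(comps))]
}

#' Network-based statistic: component-level FWE by permutation
#'
#' Thresholds the edgewise group t statistics at the two-sided critical
#' value for `primary_p`, decomposes the surviving edges into connected
#' components, and compares each observed component's extent (edge count)
#' with the permutation distribution of the maximum component extent under
#' group-label shuffling, giving family-wise-error-corrected p-values
#' \eqn{(1 + \#\{\max^* \ge k\}) / (1 + n_{perm})}.
#'
#' @param z_matrices list of [zmatrix()] objects or an [edge_matrix()].
#' @param design matrix from [design_matrix()].
#' @param primary_p two-sided cluster-forming p-value (component results
#'   depend on it; it is recorded in the output attributes).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `components` (data.frame: `component`, `size`,
#'   `p_fwe`), `component_edges` (data.frame of member edges with
#'   `component` id), `edge_stats` (the [edgewise_glm()] table with a
#'   `suprathreshold` column), `max_null` (permutation maxima); attributes
#'   `primary_p`, `t_critical`. No suprathreshold edge yields empty tables,
#'   not an error.
#' @export
nbs_fwe <- function(z_matrices, design, primary_p = 0.001, n_perm = 1000L,
                    seed = 1L) {
  stopifnot(primary_p > 0, primary_p < 1, n_perm >= 100L)
  em <- if (is.list(z_matrices) && !is.null(z_matrices$values)) z_matrices
        else edge_matrix(z_matrices)
  obs <- edgewise_glm(em, design)
  df <- attr(obs, "df")
  t_crit <- stats::qt(1 - primary_p / 2, df)
  obs$suprathreshold <- abs(obs$t) >= t_crit
  comps <- edge_components(obs, obs$suprathreshold)

  perms <- permutation_indices(nrow(design), n_perm, seed)
  t_null <- freedman_lane_t(design, em$values, attr(design, "group_col"),
                            perms)
  max_null <- vapply(seq_len(n_perm), function(b) {
    supra <- abs(t_null[b, ]) >= t_crit
    cs <- edge_components(obs, supra)
    if (length(cs)) max(lengths(cs)) else 0L
  }, numeric(1))

  if (length(comps)) {
    sizes <- lengths(comps)
    p_fwe <- vapply(sizes, function(k) (1 + sum(max_null >= k)) / (1 + n_perm),
                    numeric(1))
    components <- data.frame(component = seq_along(comps), size = sizes,
                             p_fwe = p_fwe, row.names = NULL)
    component_edges <- do.call(rbind, Map(function(id, idx) {
      cbind(component = id, obs[idx, c("i", "j", "region_i", "region_j",
                                       "effect", "t")])
    }, seq_along(comps), comps))
    rownames(component_edges) <- NULL
  } else {
    components <- data.frame(component = integer(), size = integer(),
                             p_fwe = numeric())
    component_edges <- data.frame()
  }
  out <- list(components = components, component_edges = component_edges,
              edge_stats = obs, max_null = max_null)
  attr(out, "primary_p") <- primary_p
  attr(out, "t_critical") <- t_crit
  out
}

#' Two-sample t test from summary statistics
#'
#' Computes the two-sample t from group means, standard deviations and
#' sizes, as printed in a demographics table. The default is the Welch
#' (unequal-variance) form
#' \eqn{t = (\bar x_1 - \bar x_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch-Satterthwaite degrees of freedom; the pooled-variance form is
#' available via `var_equal = TRUE`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param var_equal use the pooled-variance form.
#' @return List with `t`, `df`, `p` (two-sided); `t` is `NA` if both SDs
#'   are 0 with equal means (0/0).
#' @export
#' @examples
#' summary_t(6.15, 5.55, 67, 5.18, 5.59, 72)$t  # about 1.026
summary_t <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    if (diff == 0) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    return(list(t = Inf * sign(diff), df = n1 + n2 - 2, p = 0))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- diff / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Group comparison of AUC metrics
#'
#' Two-sample two-tailed t test per (metric, node) on the AUC values, with
#' a permutation p-value from group-label shuffles (the same shuffles
#' reused across all metric/node cells) and Benjamini-Hochberg correction
#' across the whole family. Effect summaries are the group difference of
#' means and the point-biserial correlation between group membership and
#' the AUC. Cells with zero variance in both groups have no defined t; they
#' are marked `NA`, excluded from the FDR family, and counted in the
#' `n_degenerate` attribute.
#'
#' @param auc_table data.frame with columns `subject_id`, `metric`, `node`,
#'   `auc`.
#' @param covariates data.frame with `subject_id` and `group`.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param q FDR level.
#' @param var_equal pooled-variance t if `TRUE` (default Welch).
#' @return data.frame per (metric, node): `t`, `mean_diff`
#'   (group2 - group1), `r_pb` (point-biserial), `p_perm`, `p_fdr`,
#'   `significant`.
#' @export
auc_group_test <- function(auc_table, covariates, n_perm = 1000L, seed = 1L,
                           q = 0.05, var_equal = FALSE) {
  stopifnot(all(c("subject_id", "metric", "node", "auc") %in%
                  names(auc_table)))
  covariates <- validate_covariates(covariates)
  auc_table$cell <- paste(auc_table$metric, auc_table$node, sep = "\r")
  cells <- unique(auc_table[, c("metric", "node", "cell")])
  y <- matrix(NA_real_, nrow = nrow(covariates), ncol = nrow(cells),
              dimnames = list(covariates$subject_id, cells$cell))
  idx <- cbind(match(auc_table$subject_id, covariates$subject_id),
               match(auc_table$cell, cells$cell))
  y[idx] <- auc_table$auc
  if (anyNA(y)) stop("AUC table is missing (subject, metric, node) cells")
  grp <- covariates$group == levels(covariates$group)[2L]
  n1 <- sum(!grp); n2 <- sum(grp)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 subjects")

  welch_cols <- function(yy, g) {
    m1 <- colMeans(yy[!g, , drop = FALSE]); m2 <- colMeans(yy[g, , drop = FALSE])
    v1 <- apply(yy[!g, , drop = FALSE], 2L, stats::var)
    v2 <- apply(yy[g, , drop = FALSE], 2L, stats::var)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
    }
    tt <- (m2 - m1) / se
    tt[se == 0] <- NA_real_
    list(t = tt, mean_diff = m2 - m1)
  }
  obs <- welch_cols(y, grp)
  perms <- permutation_indices(length(grp), n_perm, seed)
  exceed <- rep(0L, ncol(y))
  for (b in seq_len(n_perm)) {
    tb <- welch_cols(y, grp[perms[b, ]])$t
    exceed <- exceed + (!is.na(tb) & !is.na(obs$t) &
                          abs(tb) >= abs(obs$t))
  }
  p_perm <- ifelse(is.na(obs$t), NA_real_, (1 + exceed) / (1 + n_perm))
  p_fdr <- rep(NA_real_, length(p_perm))
  ok <- !is.na(p_perm)
  p_fdr[ok] <- stats::p.adjust(p_perm[ok], method = "BH")
  r_pb <- suppressWarnings(apply(y, 2L, function(col) {
    if (stats::sd(col) == 0) NA_real_ else stats::cor(col, as.numeric(grp))
  }))
  out <- data.frame(
    metric = cells$metric, node = cells$node,
    t = obs$t, mean_diff = obs$mean_diff, r_pb = r_pb,
    p_perm = p_perm, p_fdr = p_fdr,
    significant = !is.na(p_fdr) & p_fdr <= q,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_degenerate") <- sum(is.na(obs$t))
  out
}
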