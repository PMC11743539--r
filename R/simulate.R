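#' Community-structured baseline covariance
#'
#' Block-constant correlation matrix with unit diagonal: regions are split
#' into `n_blocks` contiguous communities with within-block correlation
#' `rho_in` and between-block correlation `rho_out`. With the defaults
#' (0.4 / 0.1, 4 blocks) the thresholded graphs sit in the clustered,
#' small-world-like regime typical of parcellated BOLD connectomes.
#'
#' @param n_regions number of regions.
#' @param n_blocks number of communities.
#' @param rho_in,rho_out within- and between-block correlations.
#' @return Symmetric positive-definite correlation matrix.
#' @export
block_covariance <- function(n_regions, n_blocks = 4L, rho_in = 0.4,
                             rho_out = 0.1) {
  stopifnot(n_regions >= 2L, n_blocks >= 1L, rho_in < 1, rho_out <= rho_in)
  blocks <- sort(rep_len(seq_len(n_blocks), n_regions))
  sigma <- matrix(rho_out, n_regions, n_regions)
  same <- outer(blocks, blocks, `==`)
  sigma[same] <- rho_in
  diag(sigma) <- 1
  labs <- paste0("R", seq_len(n_regions))
  dimnames(sigma) <- list(labs, labs)
  sigma
}

#' Simulation specification for a two-group connectome study
#'
#' Defines the generative model the synthetic cohort is drawn from:
#' zero-mean Gaussian series with a community-structured stationary
#' correlation matrix, temporally smoothed by a first-order autoregression,
#' with a group effect planted on a chosen edge set by shifting those
#' entries of the correlation matrix for group 2. Group sizes, series
#' length and covariate distributions default to the emulated study design
#' (72 control vs 67 treatment subjects, 116 regions, 240 time points, age
#' about 22 +/- 2.5 years per group, mean framewise displacement
#' half-normal).
#'
#' @param n_per_group integer pair, subjects per group (control, treatment).
#' @param n_regions,n_timepoints panel dimensions.
#' @param base_covariance stationary correlation matrix (defaults to
#'   [block_covariance()] of the right size).
#' @param effect_edges two-column matrix (or list of pairs) of region index
#'   pairs carrying the group effect.
#' @param effect_delta correlation-scale shift added to `effect_edges` for
#'   group 2. The perturbed matrix must remain positive-definite.
#' @param ar_coefficient lag-1 autoregressive coefficient in \[0, 1).
#' @param age_mean,age_sd length-2 numeric, per group.
#' @param fd_sigma length-2 numeric; mean FD is drawn half-normal with this
#'   scale (millimetres).
#' @param seed master seed for the simulation stage.
#' @return A `simulation_spec` list; errors if the perturbed covariance is
#'   not positive-definite.
#' @export
simulation_spec <- function(n_per_group = c(72L, 67L),
                            n_regions = 116L,
                            n_timepoints = 240L,
                            base_covariance = NULL,
                            effect_edges = NULL,
                            effect_delta = 0,
                            ar_coefficient = 0.3,
                            age_mean = c(21.69, 22.09),
                            age_sd = c(2.57, 2.44),
                            fd_sigma = c(0.09, 0.09),
                            seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L),
            n_regions >= 2L, n_timepoints >= 3L,
            ar_coefficient >= 0, ar_coefficient < 1)
  if (is.null(base_covariance)) base_covariance <- block_covariance(n_regions)
  stopifnot(nrow(base_covariance) == n_regions)
  if (max(abs(base_covariance - t(base_covariance))) > 1e-10) {
    stop("base_covariance must be symmetric")
  }
  if (is.list(effect_edges)) effect_edges <- do.call(rbind, effect_edges)
  if (!is.null(effect_edges)) {
    effect_edges <- matrix(as.integer(effect_edges), ncol = 2L)
    if (any(effect_edges[, 1L] == effect_edges[, 2L]) ||
        any(effect_edges < 1L) || any(effect_edges > n_regions)) {
      stop("effect_edges must be off-diagonal region index pairs")
    }
  }
  sigma2 <- perturb_covariance(base_covariance, effect_edges, effect_delta)
  # positive-definiteness of both group covariances, checked at construction
  for (s in list(base_covariance, sigma2)) {
    ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
      stop(sprintf(paste0("covariance not positive-definite (min eigenvalue ",
                          "%.3g); effect_delta = %g is too large"),
                   ev, effect_delta))
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group), n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         base_covariance = base_covariance, effect_edges = effect_edges,
         effect_delta = effect_delta, ar_coefficient = ar_coefficient,
         age_mean = age_mean, age_sd = age_sd, fd_sigma = fd_sigma,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @keywords internal
perturb_covariance <- function(sigma, effect_edges, delta) {
  if (is.null(effect_edges) || delta == 0) return(sigma)
  s <- sigma
  for (r in seq_len(nrow(effect_edges))) {
    i <- effect_edges[r, 1L]; j <- effect_edges[r, 2L]
    s[i, j] <- s[i, j] + delta
    s[j, i] <- s[i, j]
  }
  s
}

# one subject's AR(1)-colored Gaussian panel with stationary covariance sigma:
# x_t = phi x_{t-1} + e_t, Var(e) = (1 - phi^2) sigma, x_0 ~ N(0, sigma),
# so the marginal covariance is sigma at every t and lag-1 autocorrelation phi
simulate_panel_values <- function(n_timepoints, chol_stat, chol_inn, phi) {
  p <- ncol(chol_stat)
  x1 <- drop(stats::rnorm(p) %*% chol_stat)
  innov <- matrix(stats::rnorm((n_timepoints - 1L) * p),
                  n_timepoints - 1L, p) %*% chol_inn
  rest <- if (phi == 0) innov else {
    unclass(stats::filter(innov, phi, method = "recursive",
                          init = matrix(x1, 1L, p)))
  }
  unname(rbind(x1, rest))
}

#' Simulate a two-group cohort of time-series panels
#'
#' Draws every subject's panel from the spec's generative model: group 1
#' from the baseline covariance, group 2 from the baseline with
#' `effect_delta` added to the effect edges, both temporally smoothed by the
#' AR(1) coefficient and scaled to unit stationary marginal variance.
#' Covariates (age, mean framewise displacement) are drawn from the spec's
#' per-group models. Fully deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return List with `panels` (list of [ts_panel()], groups concatenated)
#'   and `covariates` (data.frame: `subject_id`, `group` in
#'   treatment/control, `age`, `mean_fd`).
#' @export
simulate_group_timeseries <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  sigma1 <- spec$base_covariance
  sigma2 <- perturb_covariance(sigma1, spec$effect_edges, spec$effect_delta)
  phi <- spec$ar_coefficient
  set.seed(child_seed(spec$seed, "simulate"))
  # group 1 is the unperturbed baseline (control); group 2 carries the
  # planted effect (treatment)
  groups <- c("control", "treatment")
  sigmas <- list(sigma1, sigma2)
  panels <- list()
  cov_rows <- list()
  for (gi in 1:2) {
    sig <- sigmas[[gi]]
    chol_stat <- chol(sig)
    chol_inn <- chol((1 - phi^2) * sig)
    for (s in seq_len(spec$n_per_group[gi])) {
      id <- sprintf("%s_%02d", substr(groups[gi], 1L, 4L), s)
      vals <- simulate_panel_values(spec$n_timepoints, chol_stat, chol_inn, phi)
      colnames(vals) <- rownames(sig)
      panels[[id]] <- ts_panel(vals, subject_id = id)
      cov_rows[[id]] <- data.frame(
        subject_id = id,
        group = groups[gi],
        age = stats::rnorm(1, spec$age_mean[gi], spec$age_sd[gi]),
        mean_fd = abs(stats::rnorm(1, 0, spec$fd_sigma[gi])),
        stringsAsFactors = FALSE
      )
    }
  }
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  list(panels = panels, covariates = validate_covariates(covariates))
}

#' Toy graphs with known structure
#'
#' Deterministic and random graph families used as fixtures for metric
#' validation: complete graph, path, star, ring lattice (each node tied to
#' its `k` nearest ring neighbors), Watts-Strogatz rewired lattice
#' (edge-count preserving), and Erdos-Renyi G(n, m).
#'
#' @param kind one of `"complete"`, `"path"`, `"star"`, `"ring_lattice"`,
#'   `"watts_strogatz"`, `"erdos_renyi"`.
#' @param n number of nodes (>= 2).
#' @param k even neighbor count for lattice/small-world kinds.
#' @param p rewiring probability for `"watts_strogatz"`.
#' @param m edge count for `"erdos_renyi"`.
#' @param seed RNG seed for the random kinds.
#' @return A [binary_graph()].
#' @export
#' @examples
#' make_toy_graph("star", 5)$n_edges  # 4
make_toy_graph <- function(kind = c("complete", "path", "star", "ring_lattice",
                                    "watts_strogatz", "erdos_renyi"),
                           n, k = NULL, p = NULL, m = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 2L) stop("toy graphs need n >= 2")
  a <- matrix(0, n, n)
  if (kind == "complete") {
    a[] <- 1; diag(a) <- 0
  } else if (kind == "path") {
    idx <- cbind(1:(n - 1L), 2:n)
    a[idx] <- 1; a[idx[, 2:1]] <- 1
  } else if (kind == "star") {
    a[1L, 2:n] <- 1; a[2:n, 1L] <- 1
  } else if (kind %in% c("ring_lattice", "watts_strogatz")) {
    if (is.null(k) || k %% 2 != 0 || k < 2 || k >= n) {
      stop("lattice kinds need an even neighbor count k with 2 <= k < n")
    }
    for (i in seq_len(n)) {
      for (offset in seq_len(k / 2)) {
        j <- (i + offset - 1L) %% n + 1L
        a[i, j] <- 1; a[j, i] <- 1
      }
    }
    if (kind == "watts_strogatz") {
      if (is.null(p) || p < 0 || p > 1) stop("watts_strogatz needs p in [0, 1]")
      set.seed(seed)
      edges <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
      for (e in seq_len(nrow(edges))) {
        if (stats::runif(1) < p) {
          i <- edges[e, 1L]
          candidates <- which(a[i, ] == 0 & seq_len(n) != i)
          if (length(candidates)) {
            jnew <- candidates[sample.int(length(candidates), 1L)]
            j <- edges[e, 2L]
            a[i, j] <- 0; a[j, i] <- 0
            a[i, jnew] <- 1; a[jnew, i] <- 1
          }
        }
      }
    }
  } else if (kind == "erdos_renyi") {
    if (is.null(m)) stop("erdos_renyi needs an edge count m")
    n_pairs <- n * (n - 1L) / 2
    if (m < 0 || m > n_pairs) stop("erdos_renyi edge count m out of range")
    set.seed(seed)
    pairs <- which(upper.tri(a), arr.ind = TRUE)
    pick <- sample.int(n_pairs, m)
    a[pairs[pick, , drop = FALSE]] <- 1
    a <- a + t(a)
  }
  binary_graph(a)
}
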