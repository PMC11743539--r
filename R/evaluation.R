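#' Type-I-error calibration study under the null
#'
#' Monte-Carlo evaluation of the pipeline's group inference when no effect
#' exists: repeatedly simulates two exchangeable groups (effect delta 0),
#' runs the edgewise permutation test and the network-based statistic on
#' each cohort, and records the edgewise rejection proportion at `alpha`
#' (uncorrected permutation p) and whether any NBS component reaches
#' family-wise significance. Under a valid procedure the mean edgewise
#' rejection rate and the NBS family-wise error both sit near `alpha`.
#'
#' @param n_replicates Monte-Carlo replicates.
#' @param n_per_group subjects per group (pair).
#' @param n_regions,n_timepoints panel dimensions per subject.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param nbs_primary_p cluster-forming p value(s) for the NBS; each is
#'   evaluated on the same simulated cohorts. At very stringent values few
#'   null datasets produce any suprathreshold edge, the max-extent null
#'   distribution degenerates at 0, and the procedure becomes conservative;
#'   a lenient value exercises the component stage properly.
#' @param seed master seed; each replicate derives its own child seeds.
#' @return List: `edge_rejection` (per-replicate proportion of edges with
#'   permutation p <= alpha), `nbs_any_rejection` (replicate x threshold
#'   logical matrix), `edge_rate`, and `nbs_fwe_rate` (named per
#'   threshold).
#' @export
null_calibration_study <- function(n_replicates = 200L,
                                   n_per_group = c(20L, 20L),
                                   n_regions = 20L, n_timepoints = 240L,
                                   n_perm = 200L, alpha = 0.05,
                                   nbs_primary_p = 0.001, seed = 1L) {
  edge_rejection <- numeric(n_replicates)
  nbs_any <- matrix(FALSE, n_replicates, length(nbs_primary_p),
                    dimnames = list(NULL, as.character(nbs_primary_p)))
  for (r in seq_len(n_replicates)) {
    rep_seed <- child_seed(seed, paste0("calibration_", r))
    spec <- simulation_spec(n_per_group = n_per_group, n_regions = n_regions,
                            n_timepoints = n_timepoints, effect_delta = 0,
                            seed = rep_seed)
    sim <- simulate_group_timeseries(spec)
    zs <- lapply(sim$panels, connectivity_matrix)
    em <- edge_matrix(zs)
    x <- design_matrix(sim$covariates)
    edge <- edgewise_fdr(em, x, n_perm = n_perm,
                         seed = child_seed(rep_seed, "edge"))
    edge_rejection[r] <- mean(edge$p_perm <= alpha)
    for (k in seq_along(nbs_primary_p)) {
      nbs <- nbs_fwe(em, x, primary_p = nbs_primary_p[k], n_perm = n_perm,
                     seed = child_seed(rep_seed, "nbs"))
      nbs_any[r, k] <- nrow(nbs$components) > 0 &&
        any(nbs$components$p_fwe <= alpha)
    }
  }
  list(edge_rejection = edge_rejection, nbs_any_rejection = nbs_any,
       edge_rate = mean(edge_rejection), nbs_fwe_rate = colMeans(nbs_any))
}

#' Power / recovery study for planted edge effects
#'
#' Monte-Carlo evaluation of the pipeline's sensitivity: plants a known
#' correlation-scale effect on a chosen edge set, simulates cohorts, and
#' measures (a) the fraction of planted edges flagged by the edgewise
#' permutation-FDR test and (b) whether the network-based statistic
#' recovers the planted edges inside a family-wise-significant component.
#'
#' @param n_replicates Monte-Carlo replicates.
#' @param n_per_group subjects per group (pair).
#' @param n_regions,n_timepoints panel dimensions per subject.
#' @param effect_edges two-column matrix of planted region pairs.
#' @param effect_delta correlation-scale shift on those edges.
#' @param n_perm_fdr permutations for the edgewise FDR test. With only a
#'   few true edges among m the BH threshold for the smallest p is about
#'   `q * n_true / m`, so the permutation floor `1/(1+n_perm_fdr)` must sit
#'   below it for recovery to be possible at all.
#' @param n_perm_nbs permutations for the NBS.
#' @param q FDR level.
#' @param fwe_alpha component-level significance threshold.
#' @param nbs_primary_p cluster-forming p for the NBS.
#' @param seed master seed.
#' @return List: `sensitivity` (per replicate, fraction of planted edges
#'   FDR-flagged), `nbs_recovered` (logical per replicate: all planted
#'   edges inside one FWE-significant component), `mean_sensitivity`,
#'   `nbs_recovery_rate`.
#' @export
effect_recovery_study <- function(n_replicates = 50L,
                                  n_per_group = c(40L, 40L),
                                  n_regions = 20L, n_timepoints = 500L,
                                  effect_edges,
                                  effect_delta = 0.3,
                                  n_perm_fdr = 2000L, n_perm_nbs = 200L,
                                  q = 0.05, fwe_alpha = 0.05,
                                  nbs_primary_p = 0.001, seed = 1L) {
  effect_edges <- matrix(as.integer(effect_edges), ncol = 2L)
  key <- paste(pmin(effect_edges[, 1], effect_edges[, 2]),
               pmax(effect_edges[, 1], effect_edges[, 2]))
  sensitivity <- numeric(n_replicates)
  recovered <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- child_seed(seed, paste0("recovery_", r))
    spec <- simulation_spec(n_per_group = n_per_group, n_regions = n_regions,
                            n_timepoints = n_timepoints,
                            effect_edges = effect_edges,
                            effect_delta = effect_delta, seed = rep_seed)
    sim <- simulate_group_timeseries(spec)
    zs <- lapply(sim$panels, connectivity_matrix)
    em <- edge_matrix(zs)
    x <- design_matrix(sim$covariates)
    edge <- edgewise_fdr(em, x, n_perm = n_perm_fdr,
                         seed = child_seed(rep_seed, "edge"), q = q)
    edge_key <- paste(edge$i, edge$j)
    sensitivity[r] <- mean(edge$significant[edge_key %in% key])
    nbs <- nbs_fwe(em, x, primary_p = nbs_primary_p, n_perm = n_perm_nbs,
                   seed = child_seed(rep_seed, "nbs"))
    recovered[r] <- FALSE
    sig <- nbs$components$component[nbs$components$p_fwe <= fwe_alpha]
    for (comp in sig) {
      ce <- nbs$component_edges[nbs$component_edges$component == comp, ]
      if (all(key %in% paste(ce$i, ce$j))) {
        recovered[r] <- TRUE
        break
      }
    }
  }
  list(sensitivity = sensitivity, nbs_recovered = recovered,
       mean_sensitivity = mean(sensitivity),
       nbs_recovery_rate = mean(recovered))
}
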