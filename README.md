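# netsweep

Sparsity-swept graph topology analysis of resting-state functional
connectomes, for two-group (treatment vs control) pharmaco-fMRI designs.

Neuroimaging groups comparing brain-network organization between two
cohorts face a standard chain of steps, each with conventions that are
easy to get subtly wrong: Pearson/Fisher-z connectivity from parcellated
BOLD time series, proportional-threshold binarization across a range of
network densities, graph metrics with defensible conventions for
disconnected graphs and low-degree nodes, area-under-curve summaries that
remove the dependence on any single threshold, and permutation-based group
inference with multiple-comparison control. netsweep packages that chain
as tested, seed-deterministic functions, together with a synthetic cohort
generator so every stage can be validated without access to raw imaging
data.

## The model

For each subject, regional time series $x_i(t)$ give a connectome
$z_{ij} = \operatorname{arctanh}(r_{ij})$ from pairwise Pearson
correlations. At each sparsity $s \in \{0.10, 0.11, \dots, 0.50\}$ the
$k = \operatorname{round}(s\,N(N-1)/2)$ strongest edges are kept, giving a
binary graph on which the package computes degree, clustering coefficient
$C = \frac{1}{N}\sum_i 2T_i/(k_i(k_i-1))$, characteristic path length
$L$, global efficiency
$E_{glob} = \frac{1}{N(N-1)}\sum_{i \ne j} 1/d_{ij}$, local efficiency,
betweenness, nodal path length and nodal efficiency, plus a nodal
small-world propensity against random-network nulls

$$\gamma_i = \frac{C_i^{obs}}{C_i^{rand}} \times \frac{L_i^{obs}}{L_i^{rand}},$$

with a degree-preserving (Maslov–Sneppen) or Erdős–Rényi G(n,m) null
ensemble. Each metric's sparsity curve is reduced to its trapezoidal AUC.
Group differences are tested three ways, never mixed: edgewise
permutation tests with Benjamini–Hochberg FDR, network-based-statistic
(NBS) component inference with max-statistic family-wise-error control,
and two-sample tests on AUC metrics — all with Freedman–Lane residual
permutation when age and head-motion (mean framewise displacement)
covariates are included.

## A worked example

Simulate a 12 + 12 subject cohort with a planted connectivity increase on
two connected edges, then test every edge:

```r
library(netsweep)

spec <- simulation_spec(
  n_per_group = c(12L, 12L), n_regions = 20L, n_timepoints = 120L,
  effect_edges = rbind(c(1L, 6L), c(6L, 11L)), effect_delta = 0.35,
  seed = 42L
)
sim <- simulate_group_timeseries(spec)
zs  <- lapply(sim$panels, connectivity_matrix)
res <- edgewise_fdr(zs, design_matrix(sim$covariates),
                    n_perm = 5000L, seed = 42L)
head(res[order(res$p_fdr, -abs(res$t)), -(1:2)], 4)
#>     region_i region_j effect     t p_perm p_fdr significant
#> 90        R6      R11  0.413 10.54 0.0002 0.019        TRUE
#> 5         R1       R6  0.352  9.09 0.0002 0.019        TRUE
#> 4         R1       R5 -0.101 -2.93 0.0086 0.545       FALSE
#> 171      R14      R16  0.110  2.62 0.0184 0.646       FALSE
```

Exactly the two planted edges survive FDR: `effect` is the group
difference on the Fisher-z scale (≈ arctanh(0.1 + 0.35) − arctanh(0.1),
as planted), `p_perm` the label-permutation p-value (floored at
1/(1+5000)), and `p_fdr` its BH adjustment across all 190 edges. The same
cohort through the NBS (`nbs_fwe()`) finds the two edges as one connected
component with family-wise p ≈ 0.016 at 500 permutations.

Threshold-free metric summaries for one subject:

```r
sm <- sweep_metrics(build_sweep(zs[[1]]))
sm$auc[sm$auc$node == "GLOBAL", ]
#>              metric   node   auc
#> 1        clustering GLOBAL 0.264
#> 2 global_efficiency GLOBAL 0.207
#> 3  local_efficiency GLOBAL 0.307
#> 4       path_length GLOBAL 0.810
```

Each AUC integrates the metric over the 0.10–0.50 sparsity range (so a
constant metric value $c$ would give $0.4c$). `run_pipeline()` chains all
stages over a directory of subject TSVs and writes tables plus a
`manifest.json` with configuration, seed and per-file checksums;
`inst/cli/netsweep` exposes the same stages as shell subcommands
(`simulate`, `connectivity`, `sweep`, `metrics`, `swp`, `nbs`,
`group-compare`, `run-all`).

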