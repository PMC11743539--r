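---
title: "Sparsity-swept topology analysis of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsity-swept topology analysis of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsweep)
```

## The analysis in one paragraph

netsweep implements a standard resting-state functional-connectome topology
pipeline for a two-group (treatment vs control) study. Each subject
contributes a region-by-time BOLD matrix (e.g. 116 AAL regions by 240 time
points). Pairwise Pearson correlations between regional time series are
Fisher-transformed, $z = \operatorname{arctanh}(r)$, giving a symmetric
z-matrix per subject — the functional connectome. Because graph metrics on
weighted matrices are confounded by overall connectivity strength, each
z-matrix is binarized by proportional thresholding at every sparsity from
10% to 50% of possible edges in 1% steps (41 graphs per subject). Global
and nodal graph metrics are computed at every sparsity, each metric curve
is reduced to its trapezoidal area under the curve (AUC), and group
differences are tested on those AUCs, on the individual edges, and on
connected components of edges.

## Connectivity and screening

`pearson_fc()` requires non-constant regional series and returns a
correlation matrix with unit diagonal; `fisher_z()` maps it off-diagonally
through arctanh and zeroes the diagonal. Off-diagonal correlations at
exactly $\pm 1$ are an error rather than being clipped: they indicate
duplicated regions, and silently clipping an infinite z-value would
distort every downstream metric for that subject.

Cohorts are screened for outliers with a 3-standard-deviation rule on the
per-subject mean off-diagonal z (`screen_outliers()`). Subjects are
flagged and reported, never dropped automatically; the skewness and excess
kurtosis of the per-subject means are reported descriptively and never
gate the pipeline.

## Thresholding and the sparsity sweep

`proportional_threshold()` retains exactly
$k = \operatorname{round}(s \cdot N(N-1)/2)$ edges at sparsity $s$,
rounding half away from zero so that $s \mapsto k$ is a fixed pure
function. Two conventions are deliberate:

* **Negative correlations.** The default `signed` mode ranks edges by raw
  z, so the retained "strongest connections" are the strongest *positive*
  couplings; `absolute` mode (rank by $|z|$) is available by
  configuration, since both readings of proportional thresholding are in
  circulation.
* **Ties.** Exact ties at the cutoff are resolved in lexicographic
  $(i, j)$ order. Ties have probability zero for real-valued data but must
  not be implementation-defined, or re-running on another platform could
  change a graph.

Graphs are not forced to be connected at low sparsity; disconnection is
handled by metric conventions instead (below). When all weights are
distinct the 41 edge sets are nested, which the tests assert.

## Graph metrics and their conventions

For a binary undirected graph with adjacency $A$, $N$ nodes and shortest
path lengths $d_{ij}$:

* degree $k_i = \sum_j A_{ij}$;
* clustering $C_i = 2T_i / (k_i(k_i-1))$, with $T_i$ the triangles at
  node $i$; the network value is the mean over *all* $N$ nodes, and nodes
  with $k_i < 2$ contribute 0 (the printed normalization divides by $N$,
  not by the count of eligible nodes);
* characteristic path length $L$ = mean $d_{ij}$ over reachable ordered
  pairs;
* global efficiency $E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$
  with $1/\infty = 0$ for unreachable pairs;
* local efficiency $E_{loc,i}$ = global efficiency of the subgraph induced
  on $i$'s neighbors ($i$ excluded), 0 when $k_i < 2$;
* nodal path length = mean $d_{ij}$ from $i$ to the nodes it can reach
  (undefined, `NA`, for isolated nodes); this is the declared
  interpretation of the per-region "node path" quantity, recorded as such
  in run manifests;
* nodal efficiency $= \frac{1}{N-1} \sum_{j \ne i} 1/d_{ij}$, whose node
  mean equals $E_{glob}$ exactly;
* betweenness centrality, unnormalized, with fractional credit across
  equal-length geodesics.

Shortest paths, local clustering and betweenness are computed through
igraph; every convention above is applied explicitly in package code, and
the test suite checks all metrics against brute-force oracles (hand-rolled
BFS, exhaustive triangle counting, geodesic counting by dynamic
programming) on every labeled graph with up to 5 nodes and on hundreds of
random graphs up to 40 nodes, at 1e-12.

`auc_over_sparsity()` is the trapezoidal rule on the exact sparsity grid —
the minimal faithful quadrature when only "area under the curve" is
specified. Curve points with undefined values are dropped pairwise.

## Nodal small-world propensity

For each node the observed clustering $C_i$ and nodal path length $L_i$
are compared with their means over an ensemble of random reference
networks with the same number of nodes and edges:

$$\gamma_i = \frac{C_i^{obs}}{C_i^{rand}} \times
             \frac{L_i^{obs}}{L_i^{rand}}.$$

The multiplicative form is implemented exactly as stated: a node scores
high when clustering **and** path length both exceed the random reference.
Note this differs from the classical small-worldness coefficient, which
*divides* by the path-length ratio so that shorter-than-random paths raise
the index. Because the two indices answer different questions, the
classical quotient $\sigma_i = (C_i^{obs}/C_i^{rand}) /
(L_i^{obs}/L_i^{rand})$ is always reported alongside $\gamma_i$ in a
separate, clearly labeled column; the package does not guess intent and
never mixes the two.

Two null models are provided. The default, degree-preserving
Maslov–Sneppen double-edge swaps (10 attempted swaps per edge per
realization, proposals creating self-loops or multi-edges rejected), is
the field standard for small-world indices because it controls the degree
sequence, which otherwise inflates clustering ratios. `erdos_renyi_gnm`
matches the literal "same number of nodes and edges" reading. Graphs that
admit no valid swap (stars, complete graphs) fall back to the source graph
with a warning, which makes $\gamma_i \equiv 1$ — the correct degenerate
answer, since such a graph is its own only degree-matched rewiring. The
ensemble default of 100 realizations balances the Monte-Carlo error of the
null means (about 10%) against runtime; each sparsity level draws its own
child-seeded ensemble.

## Group inference

**Edgewise.** Each edge's Fisher z is modeled by ordinary least squares on
intercept, group, age and mean framewise displacement. Permutation
p-values come from group-label shuffles using the Freedman–Lane scheme:
residuals under the reduced (nuisance-only) model are permuted, the
reduced fit is added back, and the full-model group t is recomputed. The
same shuffles are reused across all edges, preserving the joint null
dependence. The estimator $(1 + \#\{|t^*| \ge |t|\})/(1 + n_{perm})$
avoids zero p-values. Benjamini–Hochberg correction is applied across the
edge family.

**NBS.** Edges with $|t|$ above the two-sided critical value at the
cluster-forming p-value (default 0.001, logged in every manifest because
component results depend on it) are decomposed into connected components;
each observed component's edge count is compared with the permutation
distribution of the *maximum* component extent, giving family-wise-error
corrected p-values. Both the NBS path and the edgewise-FDR path are
emitted side by side and never mixed in one table.

**AUC group tests.** Two-sample two-tailed t tests per (metric, node) on
the AUC values, with permutation p-values from label shuffles and BH-FDR
across the whole (metric, node) family. Welch's unequal-variance form is
the default throughout — applied to the published per-group demographic
summaries it reproduces the printed t values (BDI 1.025, ASQ 0.954) to
three decimals, which the pooled form does only approximately — and the
pooled form is available by flag. Cells with zero variance in both groups
have no defined statistic; they are marked `NA` and excluded from the FDR
family rather than silently given p = 1. Effect summaries (difference of
group means, point-biserial correlation) accompany each test.

## The synthetic cohort generator

No subject-level imaging data are deposited for the study this package
emulates, so `simulate_group_timeseries()` generates cohorts with the
statistical structure the analysis assumes:

* zero-mean Gaussian series with a block-structured stationary correlation
  matrix (4 communities, within-block 0.4, between-block 0.1) — enough
  community structure that thresholded graphs sit in the clustered,
  small-world-like regime;
* temporal smoothing by a first-order autoregression
  ($x_t = \phi x_{t-1} + e_t$, innovation covariance scaled by
  $1 - \phi^2$ so stationary marginal variances stay at 1 and the lag-1
  autocorrelation equals $\phi$; default $\phi = 0.3$, in the range
  typical of BOLD series after standard preprocessing);
* group effects planted directly on the correlation scale: group 2's
  covariance adds `effect_delta` to chosen edges, with
  positive-definiteness checked at construction;
* covariates mimicking the published demographics (age 22.09 ± 2.44 vs
  21.69 ± 2.57 years; mean framewise displacement half-normal with scale
  0.09 mm, matched between groups, giving means near 0.07 mm).

What the generator does **not** emulate: hemodynamic response shape,
physiological noise, scanner drift, spatial autocorrelation beyond the
block structure, and heavy-tailed motion artifacts. Passing tests
demonstrate that the pipeline's statistics behave correctly under the
stated model — calibrated nulls, recoverable planted effects — not that
any particular real-data finding is correct.

## Numerical and design choices worth knowing

* **Seed policy.** One master seed; every stage (simulation, each
  sparsity's null ensemble, each inference family) derives a child seed
  from the master seed and the stage name via a hash followed by two
  multiplicative mixing steps. The mixing matters: stage names differing
  only in a replicate counter would otherwise map to consecutive RNG
  seeds and can produce correlated streams.
* **Sample accounting.** The emulated study reports 142 recruited in one
  place, 139 in another, and 3 exclusions; only 142 − 3 = 139 is
  arithmetically consistent, so manifests record recruited, excluded and
  analyzed counts side by side without resolving the discrepancy.
* **NBS conservatism by discreteness.** With few edges and a stringent
  cluster-forming threshold, most null datasets have no suprathreshold
  edge, the max-extent null distribution degenerates at zero, and the NBS
  rejects far less often than nominal. The calibration study therefore
  measures family-wise error at a cluster-forming p of 0.05 (where the
  component stage is actually exercised; measured FWE sits at the nominal
  level) and separately checks that the stringent default never exceeds
  nominal.
* **FDR granularity.** With $m$ edges and only $n_{true}$ real effects,
  BH can only reject the smallest p-values if the permutation floor
  $1/(1+n_{perm})$ lies below $q \cdot n_{true}/m$; recovery simulations
  size their permutation count accordingly (2000 for 3 true edges among
  190).
* **Problem sizes in tests.** Simulation-based checks run at reduced but
  honest scale: calibration at 200 replicates of 20+20 subjects, 20
  regions, 240 time points, 200 permutations; recovery at 50 replicates
  of 40+40 subjects and 500 time points. Oracle sweeps cover all 1,098
  labeled graphs on up to 5 nodes plus 400 random graphs up to 40 nodes.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(
  n_per_group = c(12L, 12L), n_regions = 20L, n_timepoints = 120L,
  effect_edges = rbind(c(1L, 6L), c(6L, 11L)), effect_delta = 0.35,
  seed = 42L
)
sim <- simulate_group_timeseries(spec)
dir <- tempfile(); dir.create(dir)
for (p in sim$panels) write_timeseries(p, file.path(dir, paste0(p$subject_id, ".tsv")))

cfg <- study_config(seed = 42L, n_permutations = 500L,
                    n_null_realizations = 20L)
run_pipeline(cfg, dir, sim$covariates, file.path(dir, "results"))
```

The results directory then holds one z-matrix per subject, the outlier
report, per-sparsity metric curves, AUC tables, small-world propensity
AUCs, the edgewise test table, the NBS component tables, the AUC group
tests, and `manifest.json` with the configuration, seed, accounting and a
checksum per file. Re-running with the same seed reproduces every file
byte for byte.

## Limitations

The pipeline analyzes static, binarized, undirected graphs only — no
weighted metrics, no dynamic (windowed) connectivity, no effective
connectivity, and no partial-correlation connectivity. It starts from
cleaned region-wise time series; parcellation and preprocessing are out of
scope. The multiplicative $\gamma_i$ rewards longer-than-random paths;
users who want the classical small-world interpretation should read the
$\sigma_i$ column.
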