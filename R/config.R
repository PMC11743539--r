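#' Study configuration
#'
#' Bundle of the analysis parameters used throughout the pipeline: the
#' sparsity sweep bounds and step for proportional thresholding, the number
#' of label permutations for group inference, the Benjamini-Hochberg FDR
#' level, the NBS cluster-forming p-value, and the random-network null
#' settings for the small-world propensity index.
#'
#' Defaults follow the study design the package emulates: a 10--50% sweep in
#' 1% steps (41 densities), 1000 permutations, and FDR q = 0.05.
#'
#' @param sparsity_lo,sparsity_hi,sparsity_step sweep bounds and increment,
#'   as fractions of the \eqn{N(N-1)/2} possible edges.
#' @param n_permutations number of group-label permutations.
#' @param fdr_q Benjamini-Hochberg false-discovery level.
#' @param nbs_primary_p two-sided cluster-forming p-value for the
#'   network-based statistic. The conventional 0.001 is the default; it is
#'   recorded in every run manifest because component results depend on it.
#' @param n_null_realizations random networks per graph for the small-world
#'   propensity null ensemble.
#' @param null_model `"degree_preserving"` (Maslov-Sneppen double-edge
#'   swaps) or `"erdos_renyi_gnm"` (same number of nodes and edges).
#' @param seed master seed; per-stage child seeds are derived from it with
#'   [child_seed()].
#' @param threshold_mode `"signed"` (rank edges by z) or `"absolute"`
#'   (rank by |z|).
#' @return A `study_config` list.
#' @export
#' @examples
#' cfg <- study_config(seed = 42L)
#' cfg$sparsity_lo
study_config <- function(sparsity_lo = 0.10,
                         sparsity_hi = 0.50,
                         sparsity_step = 0.01,
                         n_permutations = 1000L,
                         fdr_q = 0.05,
                         nbs_primary_p = 0.001,
                         n_null_realizations = 100L,
                         null_model = c("degree_preserving", "erdos_renyi_gnm"),
                         seed = 1L,
                         threshold_mode = c("signed", "absolute")) {
  null_model <- match.arg(null_model)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(
    sparsity_lo > 0, sparsity_lo <= sparsity_hi, sparsity_hi <= 1,
    sparsity_step > 0,
    n_permutations >= 1,
    fdr_q > 0, fdr_q < 1,
    nbs_primary_p > 0, nbs_primary_p < 1,
    n_null_realizations >= 1
  )
  cfg <- list(
    sparsity_lo = sparsity_lo,
    sparsity_hi = sparsity_hi,
    sparsity_step = sparsity_step,
    n_permutations = as.integer(n_permutations),
    fdr_q = fdr_q,
    nbs_primary_p = nbs_primary_p,
    n_null_realizations = as.integer(n_null_realizations),
    null_model = null_model,
    seed = as.integer(seed),
    threshold_mode = threshold_mode
  )
  class(cfg) <- "study_config"
  cfg
}

#' Derive a per-stage child seed from the master seed
#'
#' Each pipeline stage (simulation, permutation inference, null ensembles,
#' ...) seeds its own RNG stream with a child seed derived deterministically
#' from the master seed and the stage name, so stages are individually
#' reproducible and do not share streams.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  # polynomial hash of the stage name, then multiplicative mixing with the
  # master seed so that near-identical stage names (e.g. trailing replicate
  # numbers) land on well-separated seeds
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  x <- (as.numeric(seed) %% 2147483647 + h) %% 2147483647
  x <- (x * 48271) %% 2147483647      # Lehmer step
  x <- (x * 69621) %% 2147483647      # and again with a different multiplier
  as.integer(x)
}

#' Read / write a study configuration as YAML or JSON
#'
#' Format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config a `study_config`.
#' @param path file path.
#' @return `read_config()` returns a `study_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(study_config, x)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  sparsity sweep : %.2f to %.2f by %.2f (%s mode)\n",
              x$sparsity_lo, x$sparsity_hi, x$sparsity_step, x$threshold_mode))
  cat(sprintf("  permutations   : %d (FDR q = %g, NBS primary p = %g)\n",
              x$n_permutations, x$fdr_q, x$nbs_primary_p))
  cat(sprintf("  null model     : %s x %d realizations\n",
              x$null_model, x$n_null_realizations))
  cat(sprintf("  master seed    : %d\n", x$seed))
  invisible(x)
}
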