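#' Run the full connectome-topology pipeline
#'
#' Orchestrates every stage on a directory of per-subject time-series TSVs:
#' Fisher-z connectivity, outlier screening, the proportional-threshold
#' sparsity sweep, global/nodal graph metrics with AUC summaries, nodal
#' small-world propensity against random nulls, and group inference
#' (edgewise permutation FDR, NBS component FWE, AUC t-tests). All outputs
#' are written as TSV tables plus a JSON manifest recording the
#' configuration, seed, subject accounting, and a checksum for every file;
#' re-running with the same seed reproduces every numeric output exactly.
#'
#' @param config a [study_config()].
#' @param timeseries_dir directory containing `<subject_id>.tsv` panels.
#' @param covariates covariate data.frame (see [read_covariates()]); every
#'   listed subject must have a time-series file.
#' @param out_dir output directory (created if needed).
#' @param recruited,excluded optional study-accounting counts recorded in
#'   the manifest alongside the analyzed count.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, timeseries_dir, covariates, out_dir,
                         recruited = NULL, excluded = NULL) {
  stopifnot(inherits(config, "study_config"))
  covariates <- validate_covariates(covariates)
  files <- file.path(timeseries_dir, paste0(covariates$subject_id, ".tsv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("no time-series file for subject(s): ",
         paste(covariates$subject_id[missing], collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()

  # connectivity
  z_matrices <- vector("list", nrow(covariates))
  names(z_matrices) <- covariates$subject_id
  for (i in seq_len(nrow(covariates))) {
    panel <- read_timeseries(files[i], subject_id = covariates$subject_id[i])
    zm <- connectivity_matrix(panel)
    f <- file.path(out_dir, paste0("zmatrix_", zm$subject_id, ".tsv"))
    write_matrix(zm$z, f)
    outputs <- c(outputs, f)
    z_matrices[[i]] <- zm
  }
  outliers <- screen_outliers(z_matrices)
  f <- file.path(out_dir, "outlier_report.tsv")
  utils::write.table(outliers, f, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, f)

  # sweep + metrics + AUC per subject
  metric_rows <- list()
  auc_rows <- list()
  swp_auc_rows <- list()
  for (i in seq_len(nrow(covariates))) {
    id <- covariates$subject_id[i]
    sweep <- build_sweep(z_matrices[[i]], config$sparsity_lo,
                         config$sparsity_hi, config$sparsity_step,
                         mode = config$threshold_mode)
    sm <- sweep_metrics(sweep)
    sm$curves$subject_id <- id
    sm$auc$subject_id <- id
    metric_rows[[id]] <- sm$curves
    auc_rows[[id]] <- sm$auc
    sw <- sweep_swp(sweep, model = config$null_model,
                    n_realizations = config$n_null_realizations,
                    seed = child_seed(config$seed, paste0("swp_", id)))
    sw$auc$subject_id <- id
    swp_auc_rows[[id]] <- sw$auc
  }
  metric_tab <- do.call(rbind, metric_rows)
  auc_tab <- do.call(rbind, auc_rows)
  swp_tab <- do.call(rbind, swp_auc_rows)
  for (nm in c("metrics_by_sparsity", "auc", "swp_auc")) {
    tab <- switch(nm, metrics_by_sparsity = metric_tab, auc = auc_tab,
                  swp_auc = swp_tab)
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  # group inference
  design <- design_matrix(covariates)
  em <- edge_matrix(z_matrices)
  edge_tab <- edgewise_fdr(em, design, n_perm = config$n_permutations,
                           seed = child_seed(config$seed, "edgewise"),
                           q = config$fdr_q)
  f <- file.path(out_dir, "edge_tests.tsv")
  utils::write.table(edge_tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, f)

  nbs <- nbs_fwe(em, design, primary_p = config$nbs_primary_p,
                 n_perm = max(config$n_permutations, 100L),
                 seed = child_seed(config$seed, "nbs"))
  f <- file.path(out_dir, "nbs_components.tsv")
  utils::write.table(nbs$components, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, f)
  f <- file.path(out_dir, "nbs_component_edges.tsv")
  utils::write.table(nbs$component_edges, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, f)

  full_auc <- rbind(auc_tab[, c("subject_id", "metric", "node", "auc")],
                    swp_tab[, c("subject_id", "metric", "node", "auc")])
  # keep only (metric, node) cells defined for every subject
  cell <- paste(full_auc$metric, full_auc$node, sep = "\r")
  bad_cells <- unique(cell[is.na(full_auc$auc)])
  full_auc <- full_auc[!(cell %in% bad_cells), ]
  auc_tests <- auc_group_test(full_auc, covariates,
                              n_perm = config$n_permutations,
                              seed = child_seed(config$seed, "auc_tests"),
                              q = config$fdr_q)
  f <- file.path(out_dir, "auc_group_tests.tsv")
  utils::write.table(auc_tests, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, f)

  manifest <- list(
    config = unclass(config),
    nbs_primary_p = config$nbs_primary_p,
    subjects = list(
      recruited = recruited,
      excluded = excluded,
      analyzed = nrow(covariates),
      flagged_outliers = sum(outliers$flagged)
    ),
    nodal_path_definition = "mean shortest path length to reachable nodes",
    files = lapply(outputs, function(fp) {
      list(name = basename(fp), md5 = unname(tools::md5sum(fp)))
    })
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
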