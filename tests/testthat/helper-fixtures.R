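# Shared fixtures built in code.

# symmetric zero-diagonal matrix of distinct weights
distinct_zmatrix <- function(n, seed = 1) {
  set.seed(seed)
  z <- matrix(0, n, n)
  w <- sample(seq(-1.5, 1.5, length.out = n * (n - 1) / 2))
  z[upper.tri(z)] <- w
  zmatrix(z + t(z))
}

# tiny two-group cohort of z matrices with an optional mean shift on a set
# of edges for the second group (direct on the z scale; no time series)
shifted_cohort <- function(n1, n2, n_nodes, shift_edges = NULL, shift = 0,
                           noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  make_z <- function(id, shifted) {
    z <- matrix(0, n_nodes, n_nodes)
    vals <- rnorm(n_pairs, mean = 0.2, sd = noise_sd)
    z[upper.tri(z)] <- vals
    z <- z + t(z)
    if (shifted && !is.null(shift_edges)) {
      for (r in seq_len(nrow(shift_edges))) {
        i <- shift_edges[r, 1]; j <- shift_edges[r, 2]
        z[i, j] <- z[i, j] + shift
        z[j, i] <- z[i, j]
      }
    }
    zmatrix(z, subject_id = id)
  }
  zs <- c(
    lapply(seq_len(n1), function(s) make_z(sprintf("ctl_%02d", s), FALSE)),
    lapply(seq_len(n2), function(s) make_z(sprintf("trt_%02d", s), TRUE))
  )
  covariates <- data.frame(
    subject_id = vapply(zs, `[[`, character(1), "subject_id"),
    group = rep(c("control", "treatment"), c(n1, n2)),
    age = rnorm(n1 + n2, 22, 2.5),
    mean_fd = abs(rnorm(n1 + n2, 0, 0.09)),
    stringsAsFactors = FALSE
  )
  list(z_matrices = zs, covariates = covariates)
}

# write a simulated cohort to a temporary directory of TSV panels
write_sim_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in sim$panels) {
    write_timeseries(p, file.path(dir, paste0(p$subject_id, ".tsv")))
  }
  dir
}
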