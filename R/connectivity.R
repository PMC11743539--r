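#' Pearson functional connectivity
#'
#' Correlates every pair of regional time series, the standard static
#' functional-connectivity estimate for parcellated BOLD data.
#'
#' @param panel a [ts_panel()] (or a bare time-by-region matrix).
#' @return Symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\], dimnames set to the region names.
#' @export
#' @examples
#' p <- ts_panel(matrix(rnorm(50 * 4), 50, 4))
#' r <- pearson_fc(p)
#' range(diag(r))
pearson_fc <- function(panel) {
  m <- if (inherits(panel, "ts_panel")) panel$values else as.matrix(panel)
  if (nrow(m) < 3L) stop("need at least 3 time points for correlation")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    stop("degenerate correlation: constant region(s): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(m)
  r <- (r + t(r)) / 2           # kill floating-point asymmetry
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies the variance-stabilizing transform \eqn{z = \mathrm{arctanh}(r)}
#' to every off-diagonal entry and zeroes the diagonal, yielding the
#' functional connectome actually analyzed downstream. Off-diagonal
#' correlations at exactly +/-1 map to infinite z and indicate duplicated
#' regions; they are an error rather than being clipped.
#'
#' @param r correlation matrix with entries in \[-1, 1\].
#' @param subject_id subject label carried on the result.
#' @return A `zmatrix`: list with `z` (symmetric, zero diagonal),
#'   `region_names`, `subject_id`.
#' @export
fisher_z <- function(r, subject_id = "subject") {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (max(abs(r)) > 1 + 1e-12) stop("correlations must lie in [-1, 1]")
  off <- upper.tri(r)
  if (any(abs(r[off]) >= 1)) {
    idx <- which(abs(r) >= 1 & off, arr.ind = TRUE)[1L, ]
    labs <- rownames(r)
    pair <- if (is.null(labs)) paste(idx, collapse = ", ") else
      paste(labs[idx], collapse = ", ")
    stop("infinite Fisher z: |r| = 1 off-diagonal for region pair (", pair, ")")
  }
  z <- atanh(r)
  diag(z) <- 0
  labs <- rownames(r)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(r)))
  dimnames(z) <- list(labs, labs)
  zmatrix(z, region_names = labs, subject_id = subject_id)
}

#' Construct a Fisher-z connectivity matrix object
#'
#' @param z symmetric numeric matrix with zero diagonal and finite
#'   off-diagonal entries.
#' @param region_names region labels.
#' @param subject_id subject label.
#' @return A `zmatrix` list.
#' @export
zmatrix <- function(z, region_names = NULL, subject_id = "subject") {
  stopifnot(is.matrix(z), nrow(z) == ncol(z))
  if (max(abs(z - t(z))) > 1e-10) stop("z matrix is not symmetric")
  if (any(diag(z) != 0)) stop("z matrix diagonal must be exactly 0")
  if (any(!is.finite(z))) stop("z matrix has non-finite entries")
  if (is.null(region_names)) {
    region_names <- rownames(z)
    if (is.null(region_names)) region_names <- paste0("R", seq_len(nrow(z)))
  }
  dimnames(z) <- list(region_names, region_names)
  structure(
    list(z = z, region_names = as.character(region_names),
         subject_id = as.character(subject_id)),
    class = "zmatrix"
  )
}

#' @export
print.zmatrix <- function(x, ...) {
  cat(sprintf("Fisher-z connectivity matrix '%s': %d regions\n",
              x$subject_id, nrow(x$z)))
  invisible(x)
}

#' Full connectivity step for one panel
#'
#' Convenience composition of [pearson_fc()] and [fisher_z()].
#'
#' @param panel a [ts_panel()].
#' @return A [zmatrix()].
#' @export
connectivity_matrix <- function(panel) {
  fisher_z(pearson_fc(panel), subject_id = panel$subject_id)
}

#' Screen a cohort of connectomes for outliers
#'
#' Flags subjects whose mean off-diagonal Fisher z deviates from the cohort
#' mean by more than `sd_limit` cohort standard deviations. Subjects are
#' flagged and reported, never dropped; exclusion is the analyst's decision.
#' Skewness and excess kurtosis of the per-subject means are reported
#' descriptively alongside.
#'
#' @param z_matrices list of [zmatrix()] objects (>= 3 subjects).
#' @param sd_limit flagging threshold in cohort standard deviations
#'   (default 3).
#' @return data.frame with columns `subject_id`, `mean_z`, `deviation_sd`,
#'   `flagged`, plus attributes `skewness` and `excess_kurtosis`.
#' @export
screen_outliers <- function(z_matrices, sd_limit = 3) {
  if (length(z_matrices) < 3L) {
    stop("outlier screening needs at least 3 subjects for a cohort reference")
  }
  mean_z <- vapply(z_matrices, function(zm) {
    z <- if (inherits(zm, "zmatrix")) zm$z else zm
    mean(z[upper.tri(z)])
  }, numeric(1))
  ids <- vapply(z_matrices, function(zm) {
    if (inherits(zm, "zmatrix")) zm$subject_id else NA_character_
  }, character(1))
  if (anyNA(ids)) ids <- paste0("subject", seq_along(z_matrices))
  mu <- mean(mean_z)
  sigma <- stats::sd(mean_z)
  dev <- if (sigma > 0) (mean_z - mu) / sigma else rep(0, length(mean_z))
  out <- data.frame(
    subject_id = ids,
    mean_z = mean_z,
    deviation_sd = dev,
    flagged = abs(dev) > sd_limit,
    stringsAsFactors = FALSE
  )
  centred <- mean_z - mu
  m2 <- mean(centred^2)
  attr(out, "skewness") <- if (m2 > 0) mean(centred^3) / m2^1.5 else 0
  attr(out, "excess_kurtosis") <- if (m2 > 0) mean(centred^4) / m2^2 - 3 else 0
  out
}

#' Group-mean connectivity matrix
#'
#' Element-wise mean of a list of z matrices, e.g. to summarize a treatment
#' group's connectome.
#'
#' @param z_matrices list of [zmatrix()] objects with identical regions.
#' @param subject_id label for the resulting matrix.
#' @return A [zmatrix()].
#' @export
mean_zmatrix <- function(z_matrices, subject_id = "group_mean") {
  stopifnot(length(z_matrices) >= 1L)
  zs <- lapply(z_matrices, function(zm) if (inherits(zm, "zmatrix")) zm$z else zm)
  m <- Reduce(`+`, zs) / length(zs)
  zmatrix(m, region_names = rownames(zs[[1L]]), subject_id = subject_id)
}
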