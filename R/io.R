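#' Read a region-wise BOLD time-series table
#'
#' Reads one subject's parcellated time series: a delimited text table with a
#' mandatory header row of region names, one row per time point and one
#' column per region (e.g. 240 time points by 116 AAL regions). Column order
#' is preserved.
#'
#' @param path path to the delimited file.
#' @param delimiter field separator (default tab).
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @param region_names optional character vector overriding the header.
#' @return A [ts_panel()] object.
#' @export
read_timeseries <- function(path, delimiter = "\t", subject_id = NULL,
                            region_names = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("input error: ", path, " has no data rows")
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- trimws(fields[[1L]])
  n_col <- length(header)
  if (n_col < 2L) stop("input error: fewer than 2 regions in ", path)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop(sprintf("format error: ragged row at line %d of %s (%d fields, expected %d)",
                 bad + 1L, path, widths[bad], n_col))
  }
  if (length(body) < 3L) {
    stop("input error: fewer than 3 time points in ", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(body, use.names = FALSE)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1L] - 1L
    row <- flat %/% n_col + 1L
    col <- flat %% n_col + 1L
    stop(sprintf("parse error: non-numeric cell at row %d, column %d of %s",
                 row, col, path))
  }
  m <- matrix(vals, nrow = length(body), ncol = n_col, byrow = TRUE)
  if (is.null(region_names)) region_names <- header
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ts_panel(m, region_names = region_names, subject_id = subject_id)
}

#' Construct a time-series panel
#'
#' Container for one subject's region-wise series: a time-by-region numeric
#' matrix plus region names and a subject label.
#'
#' @param values numeric matrix, time points in rows, regions in columns.
#' @param region_names region labels (defaults to colnames or `R1..Rk`).
#' @param subject_id subject label.
#' @return A `ts_panel` list with elements `values`, `region_names`,
#'   `subject_id`.
#' @export
ts_panel <- function(values, region_names = NULL, subject_id = "subject") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("time-series panel contains missing values")
  if (nrow(values) < 3L) stop("input error: fewer than 3 time points")
  if (ncol(values) < 2L) stop("input error: fewer than 2 regions")
  if (is.null(region_names)) {
    region_names <- colnames(values)
    if (is.null(region_names)) region_names <- paste0("R", seq_len(ncol(values)))
  }
  stopifnot(length(region_names) == ncol(values))
  colnames(values) <- region_names
  structure(
    list(values = values, region_names = as.character(region_names),
         subject_id = as.character(subject_id)),
    class = "ts_panel"
  )
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("Time-series panel '%s': %d time points x %d regions\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a time-series panel as TSV
#'
#' @param panel a [ts_panel()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(panel, path) {
  stopifnot(inherits(panel, "ts_panel"))
  utils::write.table(panel$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a labelled square matrix as TSV
#'
#' The on-disk dialect is tab-separated with a header row of region labels
#' and a leading `region` column of row labels; `read_matrix(write_matrix(M))`
#' reproduces `M` to within 1e-12 per entry with identical labels.
#'
#' @param m square symmetric numeric matrix with row/column names.
#' @param path file path.
#' @return `write_matrix()` the path invisibly; `read_matrix()` the matrix.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("shape error: expected a square matrix, got ",
         paste(dim(m), collapse = " x "))
  }
  if (max(abs(m - t(m))) > 1e-10) stop("matrix is not symmetric within 1e-10")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(m)))
  df <- data.frame(region = labs, m, check.names = FALSE)
  colnames(df) <- c("region", labs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop("shape error: matrix file is ", nrow(m), " x ", ncol(m))
  }
  storage.mode(m) <- "double"
  rownames(m) <- labs
  colnames(m) <- colnames(df)[-1L]
  m
}

#' Read a subject covariate table
#'
#' Expects a TSV with columns `subject_id`, `group`, `age`, `mean_fd`
#' (group label, age in years, mean framewise displacement in millimetres).
#'
#' @param path TSV file path.
#' @return A data.frame with `group` as a factor.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_covariates(df)
}

#' @keywords internal
validate_covariates <- function(df) {
  need <- c("subject_id", "group", "age", "mean_fd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("covariate table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in covariate table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df$group <- factor(df$group)
  if (nlevels(df$group) != 2L) {
    stop("covariate table must contain exactly two non-empty groups, found: ",
         paste(levels(df$group), collapse = ", "))
  }
  df
}

#' Write a covariate table as TSV
#' @param covariates data.frame as returned by [read_covariates()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a node-label file
#'
#' Two-column TSV (index, name); 1-based indices in file order.
#'
#' @param path TSV file path.
#' @return Character vector of region names ordered by index.
#' @export
read_node_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("node-label file must have two columns (index, name)")
  df[[2L]][order(as.integer(df[[1L]]))]
}
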