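#' Construct a beta-value matrix
#'
#' A `BetaMatrix` is a plain numeric matrix of methylation fractions with
#' CpG identifiers as row names and sample identifiers as column names.
#' `beta_matrix()` validates and tags the matrix; all package functions
#' accept either a tagged or an untagged matrix with the same layout.
#'
#' Beta values measure the methylated fraction at a CpG site: 0 means no
#' methylation, 1 complete methylation. Missing (masked or failed) calls
#' are stored as `NA`.
#'
#' @param values Numeric matrix, CpG sites in rows, samples in columns.
#' @param cpg_ids Optional character vector of CpG IDs (defaults to
#'   `rownames(values)`).
#' @param sample_ids Optional character vector of sample IDs (defaults to
#'   `colnames(values)`).
#' @return A validated numeric matrix of class `BetaMatrix`.
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' b <- beta_matrix(m)
#' @export
beta_matrix <- function(values, cpg_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (!is.null(cpg_ids)) rownames(values) <- cpg_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_beta_matrix(values)
  class(values) <- c("BetaMatrix", class(values))
  values
}

#' Validate the layout and value range of a beta matrix
#'
#' @param values Numeric matrix with CpG row names and sample column names.
#' @return Invisibly, `values`.
#' @keywords internal
validate_beta_matrix <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("beta matrix must carry CpG row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate CpG IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  rng <- suppressWarnings(range(values, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("non-missing beta values must lie in [0, 1]")
  }
  invisible(values)
}

# strip class tag, returning the plain numeric matrix
bm_values <- function(beta) {
  beta <- unclass(beta)
  validate_beta_matrix(beta)
  beta
}

#' Write a beta-style matrix as tab-separated text
#'
#' CpG sites in rows, samples in columns, header row of sample IDs, first
#' column `cpg_id`, missing values written as `NA`. The same dialect is
#' used for detection p-value matrices.
#'
#' @param beta Matrix with CpG row names and sample column names.
#' @param path Output file path.
#' @export
write_beta_matrix <- function(beta, path) {
  m <- unclass(beta)
  df <- data.frame(cpg_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta-style matrix from tab-separated text
#'
#' @param path File written by [write_beta_matrix()] (or any TSV with a
#'   `cpg_id` first column and one column per sample).
#' @return A `BetaMatrix`.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  beta_matrix(m)
}

#' Write a sample annotation sheet as tab-separated text
#' @param sheet Data frame with one row per sample (see [simulate_cohort()]).
#' @param path Output file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation sheet
#' @param path File written by [write_sample_sheet()].
#' @return Data frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Validate a sample sheet against a beta matrix
#'
#' Checks required columns, non-negative survival times, binary event
#' indicators, and agreement of sample IDs with `beta` when supplied.
#'
#' @param sheet Sample sheet data frame.
#' @param beta Optional beta matrix whose columns must match `sheet$sample_id`.
#' @return Invisibly, `sheet`.
#' @export
validate_sample_sheet <- function(sheet, beta = NULL) {
  required <- c("sample_id", "reported_subtype", "timepoint", "age", "sex",
                "CEBPA", "FLT3", "NPM1", "WT1",
                "rfs_time", "rfs_event", "os_time", "os_event")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample IDs in sheet")
  for (col in c("rfs_time", "os_time")) {
    if (any(stats::na.omit(sheet[[col]]) < 0)) stop(col, " must be >= 0")
  }
  for (col in c("rfs_event", "os_event")) {
    v <- stats::na.omit(sheet[[col]])
    if (!all(v %in% c(0, 1))) stop(col, " must be binary 0/1")
  }
  if (!is.null(beta) && !identical(sort(colnames(beta)), sort(sheet$sample_id))) {
    stop("sample IDs in sheet do not match beta matrix columns")
  }
  invisible(sheet)
}
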