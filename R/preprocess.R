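#' Mask beta values that failed the detection p-value cutoff
#'
#' Calls whose detection p-value does not pass the cutoff (p >= `alpha`)
#' are replaced with `NA`; a call passes only when p < `alpha`. Masking is
#' idempotent.
#'
#' @param beta Beta matrix.
#' @param detection_p Numeric matrix of the same shape.
#' @param alpha Detection p-value cutoff (default 0.05).
#' @return Masked `BetaMatrix`.
#' @export
mask_low_confidence <- function(beta, detection_p, alpha = 0.05) {
  m <- bm_values(beta)
  if (!identical(dim(m), dim(detection_p))) {
    stop("beta and detection_p shapes differ")
  }
  if (!is.null(rownames(detection_p)) &&
      !identical(rownames(detection_p), rownames(m))) {
    stop("beta and detection_p CpG IDs differ")
  }
  m[detection_p >= alpha] <- NA_real_
  beta_matrix(m)
}

#' Filter probes by blacklist, autosomal membership and missingness
#'
#' Removal is applied in the order blacklist, non-autosomal, missingness
#' (> `max_missing_frac` missing entries); the order affects only how
#' removals are attributed in the report, not the surviving set. Surviving
#' values are never altered.
#'
#' @param beta Beta matrix.
#' @param blacklist Character vector of CpG IDs to drop (e.g. an empirical
#'   cross-reactive probe list supplied as a file).
#' @param autosomal_ids Character vector of autosomal CpG IDs to keep;
#'   `NULL` keeps all (treats every probe as autosomal).
#' @param max_missing_frac Maximum tolerated missing fraction per CpG;
#'   a CpG with missing fraction strictly greater is removed (a site at
#'   exactly the threshold is retained).
#' @return List with `beta` (filtered) and `report` (a `filter_report`).
#' @export
filter_probes <- function(beta, blacklist = character(),
                          autosomal_ids = NULL, max_missing_frac = 0.10) {
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("max_missing_frac must lie in [0, 1]")
  }
  m <- bm_values(beta)
  ids <- rownames(m)
  keep <- rep(TRUE, nrow(m))

  in_blacklist <- keep & ids %in% blacklist
  keep <- keep & !in_blacklist
  non_autosomal <- if (is.null(autosomal_ids)) rep(FALSE, nrow(m)) else
    keep & !(ids %in% autosomal_ids)
  keep <- keep & !non_autosomal
  miss_frac <- rowMeans(is.na(m))
  too_missing <- keep & miss_frac > max_missing_frac
  keep <- keep & !too_missing

  report <- structure(list(
    n_input_cpgs = nrow(m),
    n_masked_entries = sum(is.na(m)),
    n_removed_blacklist = sum(in_blacklist),
    n_removed_nonautosomal = sum(non_autosomal),
    n_removed_missingness = sum(too_missing),
    n_output_cpgs = sum(keep),
    outlier_sample_ids = character()
  ), class = "filter_report")

  if (!any(keep)) {
    cond <- simpleError("probe filtering removed every CpG site")
    cond$report <- report
    stop(cond)
  }
  list(beta = beta_matrix(m[keep, , drop = FALSE]), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filter report\n")
  cat("  input CpGs:          ", x$n_input_cpgs, "\n")
  cat("  masked entries:      ", x$n_masked_entries, "\n")
  cat("  removed (blacklist): ", x$n_removed_blacklist, "\n")
  cat("  removed (non-autosomal):", x$n_removed_nonautosomal, "\n")
  cat("  removed (missingness):  ", x$n_removed_missingness, "\n")
  cat("  output CpGs:         ", x$n_output_cpgs, "\n")
  if (length(x$outlier_sample_ids)) {
    cat("  outlier samples:     ",
        paste(x$outlier_sample_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a filter report as a machine-readable key-value file
#' @param report A `filter_report`.
#' @param path Output file path.
#' @export
write_filter_report <- function(report, path) {
  keys <- c("n_input_cpgs", "n_masked_entries", "n_removed_blacklist",
            "n_removed_nonautosomal", "n_removed_missingness",
            "n_output_cpgs")
  lines <- paste0(keys, "\t", vapply(report[keys], as.character, ""))
  lines <- c(lines, paste0("outlier_sample_ids\t",
                           paste(report$outlier_sample_ids, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Flag outlier samples by classical multidimensional scaling
#'
#' Samples are embedded by classical MDS of their pairwise Euclidean
#' distances (missing entries ignored pairwise, with the usual rescaling
#' of [stats::dist()]). A sample is flagged when its embedding distance
#' from the coordinate-wise median point exceeds
#' `median(d) + mad_factor * mad(d)`, a robust outlyingness rule.
#'
#' @param beta Beta matrix with at least 3 samples.
#' @param n_dims Number of MDS dimensions (default 2).
#' @param mad_factor Robust flagging multiplier (default 5); `Inf`
#'   disables flagging.
#' @return Character vector of outlier sample IDs (possibly empty).
#' @export
detect_outliers_mds <- function(beta, n_dims = 2, mad_factor = 5) {
  m <- bm_values(beta)
  if (ncol(m) < 3) stop("need at least 3 samples for MDS outlier detection")
  d <- stats::dist(t(m))
  d[is.na(d)] <- 0   # samples with no overlapping probes: treat as coincident
  emb <- suppressWarnings(stats::cmdscale(d, k = min(n_dims, ncol(m) - 1)))
  center <- apply(emb, 2, stats::median)
  dist_to_center <- sqrt(colSums((t(emb) - center)^2))
  if (is.infinite(mad_factor)) return(character())
  cutoff <- stats::median(dist_to_center) +
    mad_factor * stats::mad(dist_to_center)
  colnames(m)[dist_to_center > cutoff & cutoff > 0]
}

#' Run the full preprocessing stage
#'
#' Chains [mask_low_confidence()], [filter_probes()] and
#' [detect_outliers_mds()]; outlier IDs are recorded in the report but the
#' samples are not dropped automatically.
#'
#' @inheritParams mask_low_confidence
#' @inheritParams filter_probes
#' @inheritParams detect_outliers_mds
#' @return List with `beta` and `report`.
#' @export
preprocess_beta <- function(beta, detection_p = NULL, alpha = 0.05,
                            blacklist = character(), autosomal_ids = NULL,
                            max_missing_frac = 0.10, n_dims = 2,
                            mad_factor = 5) {
  if (!is.null(detection_p)) {
    beta <- mask_low_confidence(beta, detection_p, alpha)
  }
  out <- filter_probes(beta, blacklist, autosomal_ids, max_missing_frac)
  out$report$outlier_sample_ids <-
    detect_outliers_mds(out$beta, n_dims, mad_factor)
  out
}
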