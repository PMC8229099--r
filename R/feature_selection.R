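## Dual unsupervised CpG selection: PCA loadings + low-variance/
## high-correlation (LVHC) removal, unioned over cross-validation folds.

# per-CpG median imputation (statistic from the matrix itself)
impute_median_matrix <- function(m) {
  if (!anyNA(m)) return(m)
  med <- cpp_row_medians(m)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- med[idx[, 1]]
  m
}

#' Select CpGs by largest absolute PCA loadings
#'
#' Missing values are imputed by per-CpG medians, the sample x CpG matrix
#' is mean-centered per CpG, and a PCA is computed. For each of the first
#' `n_components` principal components the `top_per_component` CpGs with
#' largest absolute loading are taken; the returned set is the
#' deduplicated union over components (so at most `n_components *
#' top_per_component` CpGs). "Most informative" is interpreted as largest
#' absolute loading. Components beyond `min(n_samples - 1, n_cpgs)` are
#' truncated with a warning.
#'
#' @param beta Beta matrix (>= 2 samples).
#' @param n_components Number of leading principal components (default 15).
#' @param top_per_component CpGs taken per component (default 20).
#' @return Character vector of selected CpG IDs.
#' @export
pca_component_select <- function(beta, n_components = 15,
                                 top_per_component = 20) {
  m <- bm_values(beta)
  if (ncol(m) < 2) stop("PCA selection needs at least 2 samples")
  m <- impute_median_matrix(m)
  max_k <- min(ncol(m) - 1, nrow(m))
  if (n_components > max_k) {
    warning("n_components truncated from ", n_components, " to ", max_k)
    n_components <- max_k
  }
  x <- t(m)                         # samples x CpGs
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  load <- abs(pc$rotation)          # CpGs x components
  picked <- character(0)
  ids <- rownames(m)
  for (k in seq_len(ncol(load))) {
    ord <- order(-load[, k], ids)
    picked <- c(picked, ids[ord[seq_len(min(top_per_component, length(ids)))]])
  }
  unique(picked)
}

#' Select CpGs by the low-variance/high-correlation (LVHC) filter
#'
#' CpGs with variance below `var_threshold` are removed. Among the
#' survivors, correlated pairs (|Pearson r| > `corr_threshold`, computed
#' on median-imputed values) are resolved greedily: scanning in
#' descending-variance order (ties broken by CpG ID), the lower-variance
#' member of each offending pair is dropped. The returned set contains no
#' pair above the correlation threshold.
#'
#' @param beta Beta matrix.
#' @param var_threshold Minimum retained per-CpG variance (default 0.1).
#' @param corr_threshold Maximum tolerated |Pearson r| (default 0.7).
#' @return Character vector of retained CpG IDs (possibly empty).
#' @export
lvhc_select <- function(beta, var_threshold = 0.1, corr_threshold = 0.7) {
  m <- bm_values(beta)
  v <- apply(m, 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  keep <- which(v >= var_threshold)
  if (!length(keep)) return(character())
  sub <- impute_median_matrix(m[keep, , drop = FALSE])
  ids <- rownames(sub)
  vv <- v[keep]
  ord <- order(-vv, ids)
  cm <- suppressWarnings(stats::cor(t(sub)))
  cm[is.na(cm)] <- 0
  alive <- rep(TRUE, length(ord))
  names(alive) <- ids
  for (i in seq_along(ord)) {
    a <- ids[ord[i]]
    if (!alive[a]) next
    if (i < length(ord)) {
      lower <- ids[ord[(i + 1):length(ord)]]
      clash <- lower[alive[lower] & abs(cm[a, lower]) > corr_threshold]
      alive[clash] <- FALSE
    }
  }
  ids[alive[ids]]
}

#' Dual unsupervised feature selection across cross-validation folds
#'
#' Samples are partitioned into `k_folds` seeded folds; for each fold both
#' selectors run on the training portion (the other k-1 folds) and every
#' CpG selected by either method in any fold is retained. Provenance
#' records which method picked each CpG in which fold.
#'
#' @param beta Beta matrix.
#' @param k_folds Number of folds (default 5; must be >= 2).
#' @param seed Integer seed for the fold partition.
#' @param n_components,top_per_component Passed to [pca_component_select()].
#' @param var_threshold,corr_threshold Passed to [lvhc_select()].
#' @return An object of class `FeatureSet`: list with `cpg_ids` (ordered
#'   unique) and `provenance` (data frame: cpg_id, method, fold).
#' @export
select_features <- function(beta, k_folds = 5, seed = 1,
                            n_components = 15, top_per_component = 20,
                            var_threshold = 0.1, corr_threshold = 0.7) {
  m <- bm_values(beta)
  if (k_folds < 2) stop("k_folds must be >= 2")
  n <- ncol(m)
  if (n < k_folds) stop("need at least k_folds samples")
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  prov <- list()
  for (f in seq_len(k_folds)) {
    train <- beta_matrix(m[, fold != f, drop = FALSE])
    pca_ids <- suppressWarnings(
      pca_component_select(train, n_components, top_per_component))
    lvhc_ids <- lvhc_select(train, var_threshold, corr_threshold)
    if (length(pca_ids)) {
      prov[[length(prov) + 1]] <-
        data.frame(cpg_id = pca_ids, method = "PCA", fold = f,
                   stringsAsFactors = FALSE)
    }
    if (length(lvhc_ids)) {
      prov[[length(prov) + 1]] <-
        data.frame(cpg_id = lvhc_ids, method = "LVHC", fold = f,
                   stringsAsFactors = FALSE)
    }
  }
  provenance <- do.call(rbind, prov)
  if (is.null(provenance)) {
    provenance <- data.frame(cpg_id = character(), method = character(),
                             fold = integer(), stringsAsFactors = FALSE)
  }
  structure(list(cpg_ids = unique(provenance$cpg_id),
                 provenance = provenance,
                 k_folds = k_folds, seed = seed),
            class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  n_pca <- length(unique(x$provenance$cpg_id[x$provenance$method == "PCA"]))
  n_lvhc <- length(unique(x$provenance$cpg_id[x$provenance$method == "LVHC"]))
  cat("FeatureSet:", length(x$cpg_ids), "CpG sites",
      sprintf("(PCA %d, LVHC %d, union over %d folds)\n",
              n_pca, n_lvhc, x$k_folds))
  invisible(x)
}

#' Write a FeatureSet as TSV (cpg_id, methods, folds)
#' @param fs A `FeatureSet`.
#' @param path Output file path.
#' @export
write_feature_set <- function(fs, path) {
  agg <- function(id, col) {
    paste(sort(unique(x = fs$provenance[[col]][fs$provenance$cpg_id == id])),
          collapse = ",")
  }
  df <- data.frame(
    cpg_id = fs$cpg_ids,
    methods = vapply(fs$cpg_ids, agg, "", col = "method"),
    folds = vapply(fs$cpg_ids, agg, "", col = "fold"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
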