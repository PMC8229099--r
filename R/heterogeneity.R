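#' Hierarchical clustering of samples into k groups
#'
#' Samples are median-imputed, clustered by agglomerative hierarchical
#' clustering (default Ward linkage on Euclidean distance) and the
#' dendrogram is cut at `k`. Cluster letters are assigned by ascending
#' mean beta across the clustered CpGs, so "A" is always the least
#' methylated cluster (ties broken by the cluster holding the lexically
#' smallest sample ID); the partition itself does not depend on sample
#' order.
#'
#' @param beta Beta matrix (samples to cluster in columns).
#' @param k Number of clusters (default 2; must be <= n samples).
#' @param linkage Linkage passed to [stats::hclust()] (default "ward.D2").
#' @param metric Distance metric passed to [stats::dist()].
#' @return A `cluster_assignment`: list with `clusters` (named character
#'   vector sample -> label), `k`, `linkage`, `metric`.
#' @export
hier_cluster <- function(beta, k = 2, linkage = "ward.D2",
                         metric = "euclidean") {
  m <- bm_values(beta)
  if (ncol(m) < k) stop("need at least k samples")
  m <- impute_median_matrix(m)
  ord <- order(colnames(m))          # order-independent tie-break
  m <- m[, ord, drop = FALSE]
  hc <- stats::hclust(stats::dist(t(m), method = metric), method = linkage)
  grp <- stats::cutree(hc, k = k)
  means <- tapply(colMeans(m), grp, mean)
  first_id <- tapply(colnames(m), grp, min)
  lab_order <- order(means, first_id)
  relabel <- stats::setNames(LETTERS[seq_len(k)], names(means)[lab_order])
  clusters <- relabel[as.character(grp)]
  names(clusters) <- colnames(m)
  structure(list(clusters = clusters, k = k, linkage = linkage,
                 metric = metric),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, ", ", x$metric, "), k = ",
      x$k, "\n", sep = "")
  print(table(x$clusters))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Enumerates every table with the observed margins; the two-sided p-value
#' is the sum of hypergeometric probabilities not exceeding that of the
#' observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Welch two-sample t-test (two-sided)
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom; the
#' unequal-variance form is used throughout.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param equal_var Must be FALSE (only the Welch form is provided).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
two_sample_ttest <- function(x, y, equal_var = FALSE) {
  if (isTRUE(equal_var)) stop("only the Welch (unequal variance) form is provided")
  x <- stats::na.omit(as.numeric(x)); y <- stats::na.omit(as.numeric(y))
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) {
    if (mean(x) == mean(y)) {
      warning("zero variance in both groups with equal means; p = 1")
      return(list(statistic = 0, df = NA_real_, p.value = 1))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p.value = 0))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}

#' Associate cluster membership with molecular and clinical features
#'
#' Binary features (each mutation flag, the derived "any mutation" OR over
#' the four genes, and sex) are tested by Fisher's exact test on the 2x2
#' cluster-by-feature table, excluding samples with unknown status from
#' the margins. Age is tested by the Welch t-test. Features with no known
#' values are skipped with a warning.
#'
#' @param assignment A 2-cluster `cluster_assignment`.
#' @param sheet Sample sheet covering the clustered samples.
#' @return Data frame: feature, n_A, n_B, summary_A, summary_B, test, p.
#' @export
associate_clusters <- function(assignment, sheet) {
  if (assignment$k != 2) stop("association requires exactly 2 clusters")
  ids <- names(assignment$clusters)
  sub <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  if (any(is.na(sub$sample_id))) stop("sheet lacks some clustered samples")
  cl <- assignment$clusters
  in_b <- cl == "B"

  mut_cols <- c("CEBPA", "FLT3", "NPM1", "WT1")
  any_mut <- apply(sub[, mut_cols], 1, function(f) {
    if (any(f %in% TRUE)) TRUE else if (all(is.na(f))) NA else
      if (any(is.na(f))) NA else FALSE
  })
  features <- c(
    stats::setNames(lapply(mut_cols, function(cc) as.logical(sub[[cc]])),
                    mut_cols),
    list(any_mutation = any_mut, sex = sub$sex == "M", age = sub$age))

  rows <- list()
  for (nm in names(features)) {
    f <- features[[nm]]
    known <- !is.na(f)
    if (!any(known)) {
      warning("feature with all-unknown values skipped: ", nm)
      next
    }
    if (nm == "age") {
      tt <- two_sample_ttest(f[known & !in_b], f[known & in_b])
      rows[[nm]] <- data.frame(
        feature = nm, n_A = sum(known & !in_b), n_B = sum(known & in_b),
        summary_A = round(mean(f[known & !in_b]), 3),
        summary_B = round(mean(f[known & in_b]), 3),
        test = "welch_t", p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      tab <- matrix(c(sum(f & !in_b & known), sum(!f & !in_b & known),
                      sum(f & in_b & known), sum(!f & in_b & known)),
                    2, 2, byrow = TRUE)
      rows[[nm]] <- data.frame(
        feature = nm, n_A = sum(known & !in_b), n_B = sum(known & in_b),
        summary_A = sum(f & !in_b & known),
        summary_B = sum(f & in_b & known),
        test = "fisher_exact", p = fisher_exact_2x2(tab),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
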