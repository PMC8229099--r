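#' Median imputation fitted on training data only
#'
#' Per-CpG medians are computed on `train` alone and substituted into the
#' missing entries of both matrices, so no information flows from
#' `apply_to` into the statistic.
#'
#' @param train Beta matrix used to compute medians.
#' @param apply_to Optional second beta matrix sharing the same CpG IDs.
#' @return List with imputed `train` and `apply_to` (NULL if not given).
#' @export
median_impute <- function(train, apply_to = NULL) {
  tm <- bm_values(train)
  med <- cpp_row_medians(tm)
  bad <- which(is.na(med))
  if (length(bad)) {
    stop("CpG(s) entirely missing in training data: ",
         paste(utils::head(rownames(tm)[bad], 5), collapse = ", "))
  }
  fill <- function(m) {
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- med[idx[, 1]]
    beta_matrix(m)
  }
  out <- list(train = fill(tm), apply_to = NULL)
  if (!is.null(apply_to)) {
    am <- bm_values(apply_to)
    if (!identical(rownames(am), rownames(tm))) {
      stop("train and apply_to must share CpG IDs in the same order")
    }
    out$apply_to <- fill(am)
  }
  out
}

# fast path: impute columns of a plain matrix with row medians computed
# on the training columns only (no validation, no class wrapping)
impute_split <- function(m, trn, val) {
  med <- cpp_row_medians(m[, trn, drop = FALSE])
  bad <- which(is.na(med))
  if (length(bad)) {
    stop("CpG(s) entirely missing in training data: ",
         paste(utils::head(rownames(m)[bad], 5), collapse = ", "))
  }
  fill <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) sub[idx] <- med[idx[, 1]]
    sub
  }
  list(train = fill(trn), val = if (length(val)) fill(val))
}

# stratified fold assignment; classes with < 2 samples get NA (kept in
# every training split, never used for validation)
stratified_folds <- function(y, k, seed, warn = TRUE) {
  set.seed(seed)
  fold <- rep(NA_integer_, length(y))
  tab <- table(y)
  small <- names(tab)[tab < 2]
  if (length(small) && warn) {
    warning("class(es) with < 2 samples excluded from stratification: ",
            paste(small, collapse = ", "))
  }
  for (cl in names(tab)[tab >= 2]) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# accuracy of an imputed-and-fitted one-vs-rest model over outer CV folds,
# with inner grid search when the grid has more than one point
outer_cv_run <- function(beta_fs, labels, family_name, grid,
                         outer_k = 5, inner_k = 3, seed = 1,
                         folds = NULL, warn = TRUE) {
  m <- bm_values(beta_fs)
  y <- factor(labels)
  stopifnot(ncol(m) == length(y))
  if (is.null(folds)) {
    folds <- stratified_folds(as.character(y), outer_k, seed, warn = warn)
  }
  accs <- numeric(outer_k)
  chosen <- vector("list", outer_k)
  preds <- rep(NA_character_, length(y))
  for (f in seq_len(outer_k)) {
    val <- which(!is.na(folds) & folds == f)
    trn <- setdiff(seq_along(y), val)
    if (!length(val)) { accs[f] <- NA_real_; next }
    imp <- impute_split(m, trn, val)
    xtr <- t(imp$train); xva <- t(imp$val)
    ytr <- droplevels(y[trn])
    params <- grid[[1]]
    if (length(grid) > 1) {
      inner_folds <- stratified_folds(as.character(ytr), inner_k,
                                      seed + 100 + f, warn = FALSE)
      grid_acc <- vapply(grid, function(par) {
        hits <- 0; tot <- 0
        for (g in seq_len(inner_k)) {
          iv <- which(!is.na(inner_folds) & inner_folds == g)
          if (!length(iv)) next
          it <- setdiff(seq_along(ytr), iv)
          iimp <- impute_split(m, trn[it], trn[iv])
          fit <- ovr_fit(t(iimp$train), droplevels(ytr[it]),
                         family_name, par, seed = seed + 1000 * f + g)
          lab <- ovr_label(fit, ovr_prob(fit, t(iimp$val)))
          hits <- hits + sum(lab == as.character(ytr[iv]))
          tot <- tot + length(iv)
        }
        if (tot == 0) NA_real_ else hits / tot
      }, numeric(1))
      params <- grid[[which.max(grid_acc)]]
    }
    fit <- ovr_fit(xtr, ytr, family_name, params, seed = seed + f)
    lab <- ovr_label(fit, ovr_prob(fit, xva))
    accs[f] <- mean(lab == as.character(y[val]))
    chosen[[f]] <- params
    preds[val] <- lab
  }
  list(accuracies = accs, chosen = chosen, predictions = preds,
       folds = folds)
}

#' Nested cross-validated selection of the best classifier family
#'
#' Each family is evaluated by outer `outer_k`-fold stratified
#' cross-validation; inside every outer training split an `inner_k`-fold
#' grid search picks the hyperparameters (accuracy criterion) before the
#' model is refit on the full outer training part and scored on the
#' held-out fold. Median imputation is fitted inside each training split
#' only, so validation data never influence the imputer or the model.
#' The best family has the highest mean outer accuracy (ties: fewer
#' hyperparameters, then name order). Classes with fewer than 2 samples
#' are excluded from stratification (always trained on) with a warning.
#'
#' @param beta_fs Beta matrix restricted to the selected features.
#' @param labels Subtype label per sample (character or factor).
#' @param model_specs Named list of [model_spec()] objects.
#' @param outer_k,inner_k Fold counts (defaults 5 and 3).
#' @param seed Integer seed.
#' @param folds Optional pre-computed outer fold vector (internal use).
#' @return A `model_report` list: per-family fold accuracies, chosen
#'   hyperparameters, mean accuracies, and `best_family`.
#' @export
nested_cv_select <- function(beta_fs, labels,
                             model_specs = default_model_specs(),
                             outer_k = 5, inner_k = 3, seed = 1,
                             folds = NULL) {
  y <- as.character(labels)
  if (is.null(folds)) folds <- stratified_folds(y, outer_k, seed)
  per_family <- list()
  for (nm in names(model_specs)) {
    spec <- model_specs[[nm]]
    run <- outer_cv_run(beta_fs, y, spec$family, spec$grid,
                        outer_k, inner_k, seed, folds = folds, warn = FALSE)
    per_family[[nm]] <- list(accuracies = run$accuracies,
                             chosen = run$chosen,
                             mean_accuracy = mean(run$accuracies,
                                                  na.rm = TRUE),
                             n_hyperparameters = length(spec$grid[[1]]))
  }
  means <- vapply(per_family, `[[`, numeric(1), "mean_accuracy")
  npar <- vapply(per_family, `[[`, numeric(1), "n_hyperparameters")
  ord <- order(-means, npar, names(per_family))
  best <- names(per_family)[ord[1]]
  structure(list(per_family = per_family, mean_accuracies = means,
                 best_family = best, outer_k = outer_k, inner_k = inner_k,
                 seed = seed, folds = folds),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Nested cross-validation report (outer", x$outer_k, "/ inner",
      x$inner_k, "folds)\n")
  ord <- order(-x$mean_accuracies)
  for (nm in names(x$mean_accuracies)[ord]) {
    cat(sprintf("  %-24s mean accuracy %.3f\n", nm, x$mean_accuracies[nm]))
  }
  cat("Best family:", x$best_family, "\n")
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of two models' fold scores
#'
#' Zero differences are dropped; the exact null distribution (via the
#' rank-sum generating recursion) is used when n <= 25 and the absolute
#' differences are untied, otherwise a normal approximation with tie and
#' continuity correction.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (>= 2) of paired
#'   per-fold scores.
#' @return List with `statistic` (V, sum of positive ranks) and `p.value`
#'   (two-sided).
#' @export
compare_models_wilcoxon <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("unequal lengths")
  if (length(scores_a) < 2) stop("need at least 2 paired scores")
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p.value = 1))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !ties) {
    ## exact: P(V <= v) via the signed-rank distribution
    p <- 2 * min(stats::psignrank(v, n), 1 - stats::psignrank(v - 1, n))
    p <- min(p, 1)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = v, p.value = p)
}

#' Fit the final one-vs-rest classifier on all labelled samples
#'
#' If the supplied [model_spec()] carries more than one grid point,
#' hyperparameters are chosen
#' by an `inner_k`-fold grid search on the full data first. Stores the
#' training medians so new samples are imputed with training statistics.
#'
#' @param beta_fs Beta matrix restricted to the selected features.
#' @param labels Subtype per sample; at least two distinct values.
#' @param spec A [model_spec()]; typically the best family from
#'   [nested_cv_select()].
#' @param seed Integer seed.
#' @param inner_k Folds for the optional grid search (default 3).
#' @return A `fitted_classifier`.
#' @export
fit_final <- function(beta_fs, labels, spec, seed = 1, inner_k = 3) {
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("need at least two classes to fit a classifier")
  m <- bm_values(beta_fs)
  stopifnot(ncol(m) == length(y))
  params <- spec$grid[[1]]
  if (length(spec$grid) > 1) {
    inner_folds <- stratified_folds(as.character(y), inner_k, seed + 7,
                                    warn = FALSE)
    acc <- vapply(spec$grid, function(par) {
      hits <- 0; tot <- 0
      for (g in seq_len(inner_k)) {
        iv <- which(!is.na(inner_folds) & inner_folds == g)
        if (!length(iv)) next
        it <- setdiff(seq_along(y), iv)
        imp <- median_impute(beta_matrix(m[, it, drop = FALSE]),
                             beta_matrix(m[, iv, drop = FALSE]))
        fit <- ovr_fit(t(unclass(imp$train)), droplevels(y[it]),
                       spec$family, par, seed = seed + 31 * g)
        lab <- ovr_label(fit, ovr_prob(fit, t(unclass(imp$apply_to))))
        hits <- hits + sum(lab == as.character(y[iv]))
        tot <- tot + length(iv)
      }
      if (tot == 0) NA_real_ else hits / tot
    }, numeric(1))
    params <- spec$grid[[which.max(acc)]]
  }
  imp <- median_impute(beta_matrix(m))
  medians <- apply(bm_values(beta_fs), 1, stats::median, na.rm = TRUE)
  fit <- ovr_fit(t(unclass(imp$train)), y, spec$family, params, seed = seed)
  structure(list(ovr = fit, family = spec$family, params = params,
                 cpg_ids = rownames(m), medians = medians,
                 classes = levels(y), seed = seed),
            class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat("One-vs-rest", x$family, "classifier:",
      length(x$classes), "classes,", length(x$cpg_ids), "CpG features\n")
  invisible(x)
}

#' Predict cytogenetic subtype for new samples
#'
#' Class probabilities are the normalized one-vs-rest scores; the label is
#' the argmax (ties: class with more training samples, then name order).
#' Samples with maximum class probability >= 0.8 are flagged
#' `subtype_suspected`, mirroring the reporting rule for re-annotating
#' undefined samples.
#'
#' @param model A `fitted_classifier`.
#' @param beta_new Beta matrix containing at least the training CpGs.
#' @return Data frame (sample_id, predicted_subtype, max_probability,
#'   subtype_suspected) with the full probability matrix in
#'   `attr(, "probabilities")`.
#' @export
predict_subtypes <- function(model, beta_new) {
  m <- bm_values(beta_new)
  missing_ids <- setdiff(model$cpg_ids, rownames(m))
  if (length(missing_ids)) {
    stop("input lacks ", length(missing_ids), " training CpG(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  m <- m[model$cpg_ids, , drop = FALSE]
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- model$medians[idx[, 1]]
  pr <- ovr_prob(model$ovr, t(m))
  lab <- ovr_label(model$ovr, pr)
  maxp <- apply(pr, 1, max)
  out <- data.frame(sample_id = colnames(m), predicted_subtype = lab,
                    max_probability = maxp,
                    subtype_suspected = maxp >= 0.8,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "probabilities") <- pr
  out
}

#' Confusion matrix and per-class precision/recall/F1
#'
#' Rows of the confusion matrix are true classes, columns predictions.
#' Undefined ratios (no predicted or no true members) are reported as 0
#' with a warning; micro-averaged recall equals the overall accuracy.
#'
#' @param pred_labels,true_labels Equal-length label vectors.
#' @param class_order Class order for the matrix; defaults to the sorted
#'   union of the true labels. Predictions outside it are an error.
#' @return A `classification_report` with `confusion`, `per_class`,
#'   `accuracy`.
#' @export
evaluate_predictions <- function(pred_labels, true_labels,
                                 class_order = NULL) {
  if (length(pred_labels) != length(true_labels)) stop("unequal lengths")
  if (is.null(class_order)) {
    class_order <- sort(unique(c(as.character(true_labels))))
  }
  bad <- setdiff(unique(as.character(pred_labels)), class_order)
  if (length(bad)) {
    stop("predicted label(s) not in class_order: ",
         paste(bad, collapse = ", "))
  }
  tl <- factor(as.character(true_labels), levels = class_order)
  pl <- factor(as.character(pred_labels), levels = class_order)
  cm <- table(true = tl, predicted = pl)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning(what, " undefined for class(es) ",
              paste(class_order[den == 0], collapse = ", "),
              "; reported as 0")
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  denom <- precision + recall
  f1 <- ifelse(denom > 0, 2 * precision * recall / denom, 0)
  structure(list(
    confusion = cm,
    per_class = data.frame(class = class_order, precision = precision,
                           recall = recall, f1 = f1,
                           support = as.numeric(rowSums(cm)),
                           row.names = NULL, stringsAsFactors = FALSE),
    accuracy = sum(tp) / length(tl)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.3f (%d/%d)\n", x$accuracy,
              sum(diag(x$confusion)), sum(x$confusion)))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Label-permutation validation of a classifier
#'
#' The observed score is the mean outer cross-validated accuracy with the
#' true labels. For each of `n_permutations` permutations the labels are
#' shuffled and the score recomputed identically; the p-value is
#' (C + 1) / (B + 1) where C counts permuted scores >= observed, so p is
#' never zero and lies in \[1/(B+1), 1\].
#'
#' @param beta_fs Beta matrix restricted to the selected features.
#' @param labels Subtype per sample.
#' @param spec A [model_spec()]; pass a single-point grid (the chosen
#'   hyperparameters) to skip the inner search under each permutation.
#' @param n_permutations Number of label permutations (default 1000).
#' @param outer_k,inner_k Fold counts.
#' @param seed Integer seed.
#' @return A `permutation_test` list with `p.value`, `observed`,
#'   `permuted` scores.
#' @export
permutation_test <- function(beta_fs, labels, spec, n_permutations = 1000,
                             outer_k = 5, inner_k = 3, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  y <- as.character(labels)
  score <- function(lab, s) {
    mean(outer_cv_run(beta_fs, lab, spec$family, spec$grid, outer_k,
                      inner_k, seed = s, warn = FALSE)$accuracies,
         na.rm = TRUE)
  }
  observed <- score(y, seed)
  set.seed(seed + 1)
  perms <- replicate(n_permutations, sample(y), simplify = FALSE)
  permuted <- vapply(seq_along(perms), function(b) {
    score(perms[[b]], seed + 1 + b)
  }, numeric(1))
  p <- (sum(permuted >= observed - 1e-12) + 1) / (n_permutations + 1)
  structure(list(p.value = p, observed = observed, permuted = permuted,
                 n_permutations = n_permutations),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed accuracy %.3f, p = %.4g (%d permutations)\n",
    x$observed, x$p.value, x$n_permutations))
  invisible(x)
}
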