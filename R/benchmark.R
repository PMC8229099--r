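#' Synthetic subtype-classification benchmark
#'
#' Runs the full desk-scale benchmark on the default synthetic cohort:
#' simulate (Table-1-style subtype frequencies, 50 signature CpGs per
#' subtype, delta-beta 0.4, noise SD 0.05, 5% missingness), preprocess,
#' dual feature selection, a stratified 66/33 train/test split of the
#' subtype-labelled diagnostic samples, nested cross-validated model
#' selection on the training two-thirds, a final fit, and evaluation on
#' the held-out third. Optionally follows with the label-permutation
#' validation of the winning model at its chosen hyperparameters.
#'
#' @param seed Integer seed driving every stage.
#' @param n_permutations If > 0, run [permutation_test()] with this many
#'   permutations after the benchmark.
#' @param sim_config Optional [simulation_config()] override (its seed is
#'   replaced by `seed`).
#' @return List with `accuracy` (held-out test accuracy in \[0, 1\]),
#'   `evaluation`, `model_report`, `classifier`, `feature_set`,
#'   `n_train`, `n_test`, and (when requested) `permutation`.
#' @export
run_subtype_benchmark <- function(seed = 1, n_permutations = 0,
                                  sim_config = NULL) {
  seed <- as.integer(seed)
  sc <- if (is.null(sim_config)) simulation_config(seed = seed) else {
    sim_config$seed <- seed
    sim_config
  }
  sim <- simulate_cohort(sc)
  pp <- preprocess_beta(sim$beta, sim$detection_p)
  fs <- select_features(pp$beta, seed = seed + 10L)

  m <- unclass(pp$beta)
  sheet <- sim$sheet
  labelled <- sheet$timepoint == "diagnosis" &
    sheet$reported_subtype != "undefined"
  ids <- sheet$sample_id[labelled]
  y <- sheet$reported_subtype[labelled]
  beta_fs <- beta_matrix(m[fs$cpg_ids, ids, drop = FALSE])

  ## stratified 66/33 split: one of three folds is the test third
  split <- stratified_folds(y, 3, seed = seed + 20L, warn = FALSE)
  test_idx <- which(!is.na(split) & split == 1)
  train_idx <- setdiff(seq_along(y), test_idx)
  b_train <- beta_matrix(m[fs$cpg_ids, ids[train_idx], drop = FALSE])
  b_test <- beta_matrix(m[fs$cpg_ids, ids[test_idx], drop = FALSE])

  report <- suppressWarnings(
    nested_cv_select(b_train, y[train_idx], seed = seed + 30L))
  classifier <- suppressWarnings(
    fit_final(b_train, y[train_idx], model_spec(report$best_family),
              seed = seed + 40L))
  pred <- predict_subtypes(classifier, b_test)
  evaluation <- suppressWarnings(
    evaluate_predictions(pred$predicted_subtype, y[test_idx],
                         class_order = sort(unique(y))))

  out <- list(accuracy = evaluation$accuracy, evaluation = evaluation,
              model_report = report, classifier = classifier,
              feature_set = fs, truth = sim$truth,
              n_train = length(train_idx), n_test = length(test_idx),
              train_labels = y[train_idx], b_train = b_train)
  if (n_permutations > 0) {
    out$permutation <- suppressWarnings(permutation_test(
      b_train, y[train_idx],
      model_spec(report$best_family, grid = list(classifier$params)),
      n_permutations = n_permutations, seed = seed + 50L))
  }
  out
}
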