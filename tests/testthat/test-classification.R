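test_that("median imputation uses training statistics only", {
  train <- bm(matrix(c(0.2, NA, 0.4,
                       0.7, 0.7, 0.7), 2, 3, byrow = TRUE))
  out <- median_impute(train)
  expect_equal(unname(out$train[1, 2]), 0.3)   # median of 0.2, 0.4

  full <- bm(matrix(stats::runif(20), 4, 5))
  expect_identical(unclass(median_impute(full)$train), unclass(full))

  tr <- bm(matrix(c(0.7, 0.7, 0.7, 0.1, 0.2, 0.3), 2, 3, byrow = TRUE))
  ap <- beta_matrix(matrix(c(NA, 0.9, 0.9, NA), 2, 2),
                    cpg_ids = rownames(tr), sample_ids = c("n1", "n2"))
  out2 <- median_impute(tr, ap)
  expect_equal(unname(out2$apply_to[1, 1]), 0.7)  # train median, not apply_to's

  allmiss <- beta_matrix(matrix(c(NA, NA, NA, 0.5, 0.5, 0.5), 2, 3,
                                byrow = TRUE),
                         cpg_ids = c("cgX", "cgY"),
                         sample_ids = c("a", "b", "c"))
  expect_error(median_impute(allmiss), "cgX")
})

test_that("nested CV finds a perfect model on separable data", {
  fx <- separable_fixture(n_per_class = 15, n_cpgs = 40, seed = 10)
  specs <- default_model_specs()[c("nearest centroid", "k-nearest neighbors",
                                   "decision tree")]
  rep <- suppressWarnings(
    nested_cv_select(fx$beta, fx$labels, model_specs = specs, seed = 2))
  expect_equal(max(rep$mean_accuracies), 1.0)
  ## structural: exactly outer_k accuracies per family
  for (fam in rep$per_family) expect_length(fam$accuracies, 5L)
})

test_that("nested CV accuracy is near chance under shuffled labels", {
  accs <- vapply(1:5, function(i) {
    set.seed(10 + i)
    b <- bm(matrix(stats::runif(30 * 100, 0.2, 0.8), 30, 100))
    labels <- sample(rep(c("x", "y"), each = 50))
    rep <- suppressWarnings(nested_cv_select(
      b, labels,
      model_specs = default_model_specs()["nearest centroid"],
      seed = 4 + i))
    rep$mean_accuracies[[1]]
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("nested CV never sees outer-validation labels (leak test)", {
  fx <- separable_fixture(n_per_class = 12, n_cpgs = 30, seed = 12)
  y <- fx$labels
  folds <- methylaml:::stratified_folds(y, 5, seed = 8, warn = FALSE)
  run1 <- methylaml:::outer_cv_run(fx$beta, y, "k-nearest neighbors",
                                   model_spec("k-nearest neighbors")$grid,
                                   folds = folds, seed = 8, warn = FALSE)
  ## poison the labels of fold 1's validation samples
  y2 <- y
  v1 <- which(!is.na(folds) & folds == 1)
  y2[v1] <- sample(rev(y[v1]))
  run2 <- methylaml:::outer_cv_run(fx$beta, y2, "k-nearest neighbors",
                                   model_spec("k-nearest neighbors")$grid,
                                   folds = folds, seed = 8, warn = FALSE)
  expect_identical(run1$chosen[[1]], run2$chosen[[1]])
  expect_identical(run1$predictions[v1], run2$predictions[v1])
})

test_that("Wilcoxon signed-rank comparison matches enumeration", {
  expect_warning(res <- compare_models_wilcoxon(rep(0.8, 5), rep(0.8, 5)),
                 "zero")
  expect_equal(res$p.value, 1)

  a <- c(0.91, 0.93, 0.90, 0.95, 0.92)
  b <- a - c(0.01, 0.02, 0.03, 0.04, 0.05)
  res <- compare_models_wilcoxon(a, b)
  expect_equal(res$p.value, 0.0625)   # 2 / 2^5, enumerating sign flips

  expect_error(compare_models_wilcoxon(0.9, 0.8), "at least 2")

  ## random paired scores vs the 2^n enumeration oracle
  for (rep_i in 1:5) {
    set.seed(200 + rep_i)
    x <- stats::runif(7)          # continuous draws: untied a.s.
    y <- stats::runif(7)
    got <- compare_models_wilcoxon(x, y)$p.value
    expect_equal(got, signed_rank_enum(x - y), tolerance = 1e-10)
  }
})

test_that("final fit predicts training centroids and is deterministic", {
  fx <- separable_fixture(n_per_class = 10, n_cpgs = 30, seed = 13)
  fit <- fit_final(fx$beta, fx$labels, model_spec("nearest centroid"),
                   seed = 1)
  pred <- predict_subtypes(fit, fx$beta)
  expect_true(all(pred$predicted_subtype %in% fx$labels))
  pr <- attr(pred, "probabilities")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)

  fit2 <- fit_final(fx$beta, fx$labels, model_spec("nearest centroid"),
                    seed = 1)
  pred2 <- predict_subtypes(fit2, fx$beta)
  expect_identical(pred$predicted_subtype, pred2$predicted_subtype)

  ## a sample equal to a class centroid gets that class
  m <- unclass(median_impute(fx$beta)$train)
  centroid <- rowMeans(m[, fx$labels == "g1"])
  probe <- beta_matrix(matrix(centroid, ncol = 1,
                              dimnames = list(rownames(m), "probe")))
  expect_equal(predict_subtypes(fit, probe)$predicted_subtype, "g1")

  expect_error(fit_final(fx$beta, rep("g1", ncol(fx$beta)),
                         model_spec("nearest centroid")), "two classes")
  sub <- beta_matrix(unclass(fx$beta)[-1, , drop = FALSE])
  expect_error(predict_subtypes(fit, sub), rownames(fx$beta)[1])
})

test_that("an interpolating family reaches training accuracy 1", {
  fx <- separable_fixture(n_per_class = 8, n_cpgs = 25, seed = 14)
  fit <- fit_final(fx$beta, fx$labels,
                   model_spec("k-nearest neighbors", grid = list(list(k = 1L))),
                   seed = 1)
  pred <- predict_subtypes(fit, fx$beta)
  expect_equal(mean(pred$predicted_subtype == fx$labels), 1.0)
})

test_that("the subtype-suspected flag fires at probability 0.80 exactly", {
  flag_for <- function(p_main) {
    ovr <- structure(list(
      family = "nearest centroid", params = list(),
      models = list(A = list(.constant = p_main),
                    B = list(.constant = 1 - p_main)),
      classes = c("A", "B"), counts = c(2, 2)), class = "ovr_fit")
    model <- structure(list(
      ovr = ovr, family = "nearest centroid", params = list(),
      cpg_ids = c("cg1", "cg2"), medians = c(cg1 = 0.5, cg2 = 0.5),
      classes = c("A", "B"), seed = 1), class = "fitted_classifier")
    b <- beta_matrix(matrix(0.5, 2, 1,
                            dimnames = list(c("cg1", "cg2"), "s1")))
    predict_subtypes(model, b)$subtype_suspected
  }
  expect_true(flag_for(0.80))
  expect_false(flag_for(0.79))
})

test_that("evaluation report reproduces standard metric definitions", {
  perfect <- evaluate_predictions(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(sum(diag(perfect$confusion)), 3L)

  ## 30 of 33 correct -> 90.9%
  truth <- rep(c("a", "b", "c"), each = 11)
  pred <- truth
  pred[c(1, 12, 23)] <- c("b", "c", "a")
  rep33 <- evaluate_predictions(pred, truth)
  expect_equal(rep33$accuracy, 30 / 33)

  one_class <- suppressWarnings(
    evaluate_predictions(rep("a", 10), rep(c("a", "b"), each = 5)))
  expect_equal(one_class$per_class$recall, c(1, 0))

  expect_error(evaluate_predictions(c("a", "z"), c("a", "b")), "z")
})

test_that("micro-averaged recall equals accuracy on random confusions", {
  for (rep_i in 1:10) {
    set.seed(300 + rep_i)
    classes <- letters[1:4]
    truth <- sample(classes, 60, replace = TRUE)
    pred <- sample(classes, 60, replace = TRUE)
    r <- suppressWarnings(evaluate_predictions(pred, truth, classes))
    cm <- r$confusion
    micro_recall <- sum(diag(cm)) / sum(cm)
    brute_acc <- mean(pred == truth)
    expect_equal(r$accuracy, brute_acc)
    expect_equal(micro_recall, brute_acc)
  }
})

test_that("permutation p-value honours the (C+1)/(B+1) convention", {
  fx <- separable_fixture(n_per_class = 10, n_cpgs = 30, seed = 15)
  spec <- model_spec("nearest centroid")
  pt <- permutation_test(fx$beta, fx$labels, spec, n_permutations = 19,
                         seed = 6)
  expect_equal(pt$observed, 1.0)
  expect_equal(pt$p.value, 1 / 20)     # observed beats every permutation
  expect_gte(pt$p.value, 1 / 20)
  expect_lte(pt$p.value, 1)
  expect_error(permutation_test(fx$beta, fx$labels, spec,
                                n_permutations = 0), "n_permutations")
})
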