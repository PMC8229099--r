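test_that("hierarchical clustering recovers a planted two-group structure", {
  fx <- separable_fixture(n_per_class = 12, n_cpgs = 50, delta = 0.4,
                          noise = 0.05, seed = 20)
  cl <- hier_cluster(fx$beta, k = 2)
  truth <- fx$labels[match(names(cl$clusters), colnames(fx$beta))]
  expect_equal(adjusted_rand(cl$clusters, truth), 1)
  ## letters assigned by ascending mean beta
  m <- unclass(fx$beta)
  mean_a <- mean(m[, names(cl$clusters)[cl$clusters == "A"]])
  mean_b <- mean(m[, names(cl$clusters)[cl$clusters == "B"]])
  expect_lt(mean_a, mean_b)
})

test_that("clustering is deterministic and supports edge cases", {
  b <- bm(matrix(0.5, 20, 6))
  c1 <- hier_cluster(b, k = 2)
  c2 <- hier_cluster(b, k = 2)
  expect_identical(c1$clusters, c2$clusters)

  singletons <- hier_cluster(bm(matrix(stats::runif(30), 10, 3)), k = 3)
  expect_equal(length(unique(singletons$clusters)), 3L)
  expect_error(hier_cluster(b, k = 7), "at least k")

  ## partition identity unaffected by sample order
  set.seed(21)
  m <- matrix(stats::runif(40 * 8), 40, 8)
  b2 <- bm(m)
  p1 <- hier_cluster(b2, k = 2)$clusters
  perm <- sample(8)
  p2 <- hier_cluster(beta_matrix(unclass(b2)[, perm]), k = 2)$clusters
  expect_equal(adjusted_rand(p1[names(p2)], p2), 1)
})

test_that("Fisher 2x2 matches enumeration and handles degeneracy", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-10)   # ~1.08e-5
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher 2x2 equals stats::fisher.test on all tables, total <= 12", {
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
      expect_equal(fisher_exact_2x2(tab),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("Welch t-test matches the closed-form statistic", {
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  res <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)

  ## |t| grows with mean separation at fixed variance
  t1 <- abs(two_sample_ttest(c(1, 2, 3), c(2, 3, 4))$statistic)
  t2 <- abs(two_sample_ttest(c(1, 2, 3), c(4, 5, 6))$statistic)
  expect_gt(t2, t1)

  expect_warning(z <- two_sample_ttest(c(2, 2), c(2, 2)), "zero variance")
  expect_equal(z$p.value, 1)
  expect_error(two_sample_ttest(1, c(1, 2)), ">= 2")
})

test_that("cluster association tests features with unknowns excluded", {
  ids <- sprintf("P%02d", 1:20)
  clusters <- stats::setNames(rep(c("A", "B"), each = 10), ids)
  assignment <- structure(list(clusters = clusters, k = 2,
                               linkage = "ward.D2", metric = "euclidean"),
                          class = "cluster_assignment")
  sheet <- data.frame(
    sample_id = ids,
    age = c(stats::rnorm(10, 4.5, 1), stats::rnorm(10, 10.8, 1)),
    sex = rep(c("F", "M"), 10),
    CEBPA = c(rep(FALSE, 10), rep(TRUE, 10)),   # only in cluster B
    FLT3 = rep(NA, 20),                         # all unknown -> skipped
    NPM1 = c(TRUE, rep(FALSE, 18), NA),         # one unknown
    WT1 = rep(FALSE, 20),
    stringsAsFactors = FALSE)
  expect_warning(tab <- associate_clusters(assignment, sheet), "FLT3")
  expect_false("FLT3" %in% tab$feature)

  cebpa <- tab[tab$feature == "CEBPA", ]
  expect_equal(cebpa$p, 2 / choose(20, 10), tolerance = 1e-10)

  npm1 <- tab[tab$feature == "NPM1", ]
  expect_equal(npm1$n_A + npm1$n_B, 19)         # unknown left out of margins

  age <- tab[tab$feature == "age", ]
  expect_lt(age$p, 0.001)
  expect_identical(age$test, "welch_t")
})

test_that("null features reject near the nominal rate", {
  set.seed(22)
  rejections <- vapply(1:100, function(i) {
    g <- rep(c(FALSE, TRUE), each = 15)
    f <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    tab <- matrix(c(sum(f & !g), sum(!f & !g), sum(f & g), sum(!f & g)),
                  2, byrow = TRUE)
    fisher_exact_2x2(tab) < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.11)   # Fisher is conservative; alpha 0.05
})
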