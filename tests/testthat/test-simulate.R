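test_that("default cohort reproduces the diagnostic class frequencies", {
  sim <- simulate_cohort(simulation_config(n_cpgs = 600, seed = 3))
  diag <- sim$sheet[sim$sheet$timepoint == "diagnosis", ]
  counts <- table(diag$reported_subtype)
  expect_equal(counts[["NK"]], 30)
  expect_equal(counts[["MLL"]], 25)
  expect_equal(counts[["undefined"]], 24)
  expect_equal(counts[["t(8;21)"]], 19)
  expect_equal(counts[["inv(16)"]], 12)
  expect_equal(counts[["mono7"]], 5)
  expect_equal(counts[["t(15;17)"]], 4)
  expect_equal(counts[["sole+8"]], 3)
  expect_equal(counts[["3q21q26"]], 1)
  expect_equal(sum(sim$sheet$timepoint == "relapse"), 19)
  expect_equal(ncol(sim$beta), 142)
})

test_that("no planted signal and no noise gives identical beta columns", {
  cfg <- simulation_config(
    n_cpgs = 100, subtype_sizes = c(a = 5, b = 5), n_signature_cpgs = 0,
    n_outcome_cpgs = 0, noise_sd = 0, missing_rate = 0,
    detection_fail_rate = 0, n_undefined = 0, n_relapse = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  m <- unclass(sim$beta)
  expect_true(all(m == m[, 1]))
})

test_that("planted mean shift matches effect_delta (Monte-Carlo)", {
  cfg <- simulation_config(
    n_cpgs = 2000, subtype_sizes = c(a = 20, b = 20), n_signature_cpgs = 40,
    effect_delta = 0.4, noise_sd = 0.05, missing_rate = 0,
    detection_fail_rate = 0, n_undefined = 0, n_relapse = 0,
    n_outcome_cpgs = 0, seed = 7)
  sim <- simulate_cohort(cfg)
  m <- unclass(sim$beta)
  ids_a <- sim$sheet$sample_id[sim$sheet$true_subtype == "a"]
  ids_b <- sim$sheet$sample_id[sim$sheet$true_subtype == "b"]
  rows <- match(sim$truth$signatures[["a"]], rownames(m))
  diff <- rowMeans(m[rows, ids_a]) - rowMeans(m[rows, ids_b])
  expect_equal(mean(abs(diff)), 0.4, tolerance = 0.03 / 0.4)
})

test_that("generation is reproducible and planted truth is disjoint", {
  cfg <- simulation_config(n_cpgs = 500, seed = 11)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$sheet, s2$sheet)
  expect_identical(s1$truth, s2$truth)
  all_sig <- unlist(s1$truth$signatures, use.names = FALSE)
  expect_equal(anyDuplicated(c(all_sig, s1$truth$outcome_cpgs)), 0L)
  expect_length(all_sig, 50 * 8)
  rng <- range(unclass(s1$beta), na.rm = TRUE)
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
})

test_that("infeasible signature demands are rejected", {
  expect_error(simulation_config(n_cpgs = 100, n_signature_cpgs = 200),
               "n_cpgs|disjoint")
  expect_error(simulation_config(missing_rate = 1.5), "rates")
})

test_that("simulate_outcomes honours censoring and hazard ratio", {
  sheet <- data.frame(sample_id = sprintf("P%03d", 1:400))
  g <- rep(c(0, 1), each = 200)
  out <- simulate_outcomes(sheet, g, hazard_ratio = 4,
                           baseline_hazard = 0.02, censor_rate = 0,
                           seed = 5)
  expect_true(all(out$rfs_event == 1))
  expect_true(all(out$os_event == 1))
  ## exponential quantile arithmetic: median_g0 / median_g1 = HR
  ratio <- stats::median(out$rfs_time[g == 0]) /
    stats::median(out$rfs_time[g == 1])
  expect_equal(ratio, 4, tolerance = 0.3)
  expect_error(simulate_outcomes(sheet, g, hazard_ratio = -1), "hazard")
})

test_that("null hazard gives uniform log-rank p over replicates", {
  ## KS check over 200 replicates with hazard_ratio = 1
  pvals <- vapply(seq_len(200), function(b) {
    sheet <- data.frame(sample_id = sprintf("P%02d", 1:40))
    g <- rep(c(0, 1), each = 20)
    out <- simulate_outcomes(sheet, g, hazard_ratio = 1,
                             baseline_hazard = 0.05, censor_rate = 0.2,
                             seed = 1000 + b)
    logrank_test(out$rfs_time, out$rfs_event, g)$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("inject_missingness controls both rates", {
  m <- bm(matrix(stats::runif(1000 * 100), 1000, 100))
  none <- inject_missingness(m, 0, 0, seed = 1)
  expect_identical(unclass(none$beta), unclass(m))
  expect_true(all(none$detection_p < 0.05))

  all_miss <- inject_missingness(m, 1, 0, seed = 1)
  expect_true(all(is.na(all_miss$beta)))

  some <- inject_missingness(m, 0.05, 0.02, seed = 2)
  frac <- mean(is.na(some$beta))
  sd3 <- 3 * sqrt(0.05 * 0.95 / length(m))
  expect_lt(abs(frac - 0.05), sd3)
})

test_that("beta matrix TSV round-trips including missing values", {
  m <- bm(matrix(c(0.1, NA, 0.5, 0.9), 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(m, path)
  back <- read_beta_matrix(path)
  expect_equal(unclass(back), unclass(m))
})
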