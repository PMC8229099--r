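test_that("relapse CpG ranking caps at top_k and needs both classes", {
  set.seed(30)
  n_cpgs <- 120
  m <- matrix(stats::runif(n_cpgs * 30, 0.3, 0.5), n_cpgs, 30)
  rel <- rep(c(1, 0), c(12, 18))
  m[1:100, rel == 1] <- m[1:100, rel == 1] + 0.35
  b <- bm(pmin(m, 1))
  ranked <- rank_outcome_cpgs(b, rel, top_k = 50)
  expect_equal(nrow(ranked), 50)
  expect_true(all(ranked$p < 0.05))
  expect_true(!is.unsorted(ranked$p))

  few <- rank_outcome_cpgs(bm(pmin(m[c(1:30, 101:120), ], 1)),
                           rel, top_k = 50)
  expect_lte(nrow(few), 50)
  expect_true(all(few$p < 0.05))
  expect_error(rank_outcome_cpgs(b, rep(0, 30)), "non-empty")
})

test_that("null relapse flags pass the raw threshold at ~alpha rate", {
  set.seed(31)
  frac <- vapply(1:30, function(i) {
    m <- matrix(stats::runif(100 * 24, 0.2, 0.8), 100, 24)
    b <- bm(m)
    rel <- sample(rep(c(0, 1), each = 12))
    mean(apply(m, 1, function(v)
      mannwhitney_u(v[rel == 1], v[rel == 0], mode = "normal")$p.value) < 0.05)
  }, numeric(1))
  expect_lt(mean(frac), 0.10)
  expect_gt(mean(frac), 0.01)
})

test_that("methylation groups are labelled by overall beta level", {
  fx <- separable_fixture(n_per_class = 10, n_cpgs = 40, delta = 0.4,
                          noise = 0.04, seed = 32)
  groups <- assign_methylation_groups(fx$beta)
  truth <- fx$labels[match(names(groups), colnames(fx$beta))]
  expect_equal(adjusted_rand(groups, truth), 1)
  m <- unclass(fx$beta)
  expect_gt(mean(m[, names(groups)[groups == "high"]]),
            mean(m[, names(groups)[groups == "low"]]))
  expect_error(assign_methylation_groups(fx$beta, k = 3), "k = 2")
})

test_that("Kaplan-Meier estimator matches hand-computed fixtures", {
  none <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(none$survival == 1))

  two <- km_curve(c(1, 2), c(1, 1))
  expect_equal(two$survival, c(1, 0.5, 0))

  ## event at 1, censor at 1.5, event at 2: S(2) = (1 - 1/3)(1 - 1/1) = 0
  cens <- km_curve(c(1, 1.5, 2), c(1, 0, 1))
  expect_equal(cens$survival[cens$time == 1], 2 / 3)
  expect_equal(cens$survival[cens$time == 2], 0)

  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(33)
  t_obs <- stats::rexp(40, 0.1)
  km <- km_curve(t_obs, rep(1, 40))
  emp <- vapply(km$time, function(tt) mean(t_obs > tt), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("KM curve agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(34)
  t_obs <- round(stats::rexp(30, 0.1), 1)
  ev <- stats::rbinom(30, 1, 0.7)
  km <- km_curve(t_obs, ev)
  sf <- survival::survfit(survival::Surv(t_obs, ev) ~ 1)
  at <- summary(sf, times = sort(unique(t_obs)))
  got <- km$survival[match(at$time, km$time)]
  expect_equal(got, at$surv, tolerance = 1e-10)
})

test_that("log-rank test matches brute force and survdiff", {
  t1 <- c(1, 2, 3, 4, 5); e1 <- c(1, 0, 1, 1, 0)
  times <- c(t1, t1); events <- c(e1, e1)
  groups <- rep(c("a", "b"), each = 5)
  same <- logrank_test(times, events, groups)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(35)
  for (i in 1:5) {
    tt <- round(stats::rexp(20, 0.2), 2)
    ee <- stats::rbinom(20, 1, 0.8)
    gg <- rep(c("a", "b"), each = 10)
    got <- logrank_test(tt, ee, gg)
    expect_equal(got$statistic, logrank_brute(tt, ee, gg),
                 tolerance = 1e-12)
    ## symmetry in group labels
    flip <- logrank_test(tt, ee, rev(gg))
    expect_equal(got$statistic,
                 logrank_test(tt, ee, ifelse(gg == "a", "b", "a"))$statistic)
    if (requireNamespace("survival", quietly = TRUE)) {
      sd <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
      expect_equal(got$statistic, unname(sd$chisq), tolerance = 1e-8)
    }
  }

  expect_warning(nop <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(nop$p.value, 1)
})

test_that("log-rank has power against a hazard ratio of 4", {
  set.seed(36)
  hits <- vapply(1:20, function(i) {
    g <- rep(c(0, 1), each = 100)
    tt <- stats::rexp(200, 0.02 * 4^g)
    logrank_test(tt, rep(1, 200), g)$p.value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Cox fit agrees with survival::coxph (Breslow)", {
  skip_if_not_installed("survival")
  set.seed(37)
  n <- 120
  x <- cbind(grp = stats::rbinom(n, 1, 0.5), z = stats::rnorm(n))
  tt <- round(stats::rexp(n, 0.05 * exp(0.8 * x[, 1] - 0.3 * x[, 2])), 1)
  ee <- stats::rbinom(n, 1, 0.8)
  fit <- cox_ph_fit(tt, ee, x)
  ref <- survival::coxph(survival::Surv(tt, ee) ~ x, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-5)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$hazard_ratios, exp(fit$coefficients))
})

test_that("Cox handles null effects, separation and bad inputs", {
  ## identical event-time multisets in both groups -> coefficient ~ 0
  tt <- rep(c(1, 2, 3, 4, 6), 2)
  ee <- rep(1, 10)
  x <- cbind(grp = rep(c(0, 1), each = 5))
  fit <- cox_ph_fit(tt, ee, x)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-6)
  expect_equal(unname(fit$hazard_ratios), 1, tolerance = 1e-6)

  expect_error(cox_ph_fit(tt, ee, cbind(rep(1, 10))), "constant")
  expect_error(cox_ph_fit(tt, rep(0, 10), x), "no events")

  ## perfect separation: group 1 events all before group 0 events
  tt2 <- c(1:5, 101:105)
  x2 <- cbind(grp = rep(c(1, 0), each = 5))
  expect_warning(sep <- cox_ph_fit(tt2, rep(1, 10), x2), "monotone")
  expect_true(sep$separation)
  expect_lte(abs(unname(sep$coefficients)), 15)
})

test_that("Cox score test at beta = 0 matches the log-rank statistic", {
  ## single binary covariate, no tied event times
  set.seed(38)
  tt <- sample(seq(1, 400) / 10, 30)
  ee <- stats::rbinom(30, 1, 0.85)
  g <- rep(c(0, 1), 15)
  if (!any(ee == 1)) ee[1] <- 1
  ## score U and information I at beta = 0 via one unconverged iteration
  x <- cbind(grp = g)
  ev_times <- sort(unique(tt[ee == 1]))
  U <- 0; I <- 0
  for (t in ev_times) {
    risk <- tt >= t
    n <- sum(risk); n1 <- sum(risk & g == 1)
    d <- sum(tt == t & ee == 1)
    d1 <- sum(tt == t & ee == 1 & g == 1)
    U <- U + d1 - d * n1 / n
    I <- I + d * (n1 / n) * (1 - n1 / n)
  }
  score_stat <- U^2 / I
  lr <- logrank_test(tt, ee, g)$statistic
  ## identical when no ties; hypergeometric variance factor (n-d)/(n-1) = 1
  expect_equal(score_stat, lr, tolerance = 1e-6)
})

test_that("the survival stage links planted methylation groups to outcome", {
  set.seed(39)
  n <- 60
  ids <- sprintf("P%03d", 1:n)
  grp <- rep(c(0, 1), each = n / 2)
  m <- matrix(stats::runif(300 * n, 0.3, 0.5), 300, n)
  m[1:60, grp == 1] <- m[1:60, grp == 1] + 0.35
  m <- pmin(pmax(m + stats::rnorm(length(m), sd = 0.05), 0), 1)
  b <- beta_matrix(m, cpg_ids = sprintf("cg%05d", 1:300), sample_ids = ids)
  sheet <- data.frame(sample_id = ids, reported_subtype = "NK",
                      timepoint = "diagnosis", stringsAsFactors = FALSE)
  sheet <- simulate_outcomes(sheet, grp, hazard_ratio = 4,
                             baseline_hazard = 0.03, censor_rate = 0.2,
                             seed = 40)
  sg <- run_survival_stage(b, sheet, "NK")
  expect_lt(sg$rfs$logrank$p.value, 0.01)
  expect_s3_class(sg$rfs$cox, "cox_fit")
  expect_true(all(sg$groups %in% c("high", "low")))
  expect_true(all(table(sg$groups) > 0))

  ## adding predicted samples grows, never shrinks, the analysis set
  sheet2 <- sheet
  sheet2$reported_subtype[1:10] <- "undefined"
  base_n <- length(run_survival_stage(b, sheet2, "NK")$sample_ids)
  more_n <- length(run_survival_stage(b, sheet2, "NK",
                                      include_predicted = TRUE,
                                      predicted = ids[1:10])$sample_ids)
  expect_gte(more_n, base_n)

  ## excluded deviants are absent
  excl <- run_survival_stage(b, sheet, "NK", exclusions = ids[1])
  expect_false(ids[1] %in% excl$sample_ids)
})
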