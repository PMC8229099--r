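## Within-subtype survival analysis: relapse-associated CpG ranking,
## methylation high/low grouping, Kaplan-Meier / log-rank / Cox.

#' Rank CpGs by association with relapse status
#'
#' Each CpG is tested by Mann-Whitney between relapse and no-relapse
#' samples; CpGs with raw p < `alpha` (no multiplicity adjustment at this
#' screening stage) are ranked by ascending p, ties broken by larger
#' absolute mean-beta difference and then CpG ID, and at most `top_k` are
#' returned.
#'
#' @param beta Beta matrix of the subtype's diagnostic samples.
#' @param relapse_flag Binary (0/1 or logical) per sample.
#' @param alpha Raw p-value threshold (default 0.05).
#' @param top_k Maximum number of CpGs returned (default 50).
#' @return Data frame (cpg_id, U, p, delta_beta), best first.
#' @export
rank_outcome_cpgs <- function(beta, relapse_flag, alpha = 0.05,
                              top_k = 50) {
  m <- bm_values(beta)
  rel <- as.logical(relapse_flag)
  stopifnot(length(rel) == ncol(m))
  if (!any(rel) || all(rel)) stop("both relapse classes must be non-empty")
  res <- apply(m, 1, function(v) {
    xs <- v[rel & !is.na(v)]; ys <- v[!rel & !is.na(v)]
    if (!length(xs) || !length(ys)) return(c(NA_real_, 1, 0))
    mw <- mannwhitney_u(xs, ys, mode = "normal")
    c(mw$statistic, mw$p.value, mean(xs) - mean(ys))
  })
  df <- data.frame(cpg_id = rownames(m), U = res[1, ], p = res[2, ],
                   delta_beta = res[3, ], stringsAsFactors = FALSE,
                   row.names = NULL)
  df <- df[df$p < alpha, , drop = FALSE]
  df <- df[order(df$p, -abs(df$delta_beta), df$cpg_id), , drop = FALSE]
  utils::head(df, top_k)
}

#' Split samples into high/low methylation groups by clustering
#'
#' Hierarchical clustering (same engine as [hier_cluster()]) cut at k = 2;
#' the cluster with the larger mean beta over the selected CpGs is
#' labelled "high" (tie: the cluster containing the lexically smallest
#' sample ID).
#'
#' @param beta_topk Beta matrix restricted to the selected CpGs.
#' @param k Number of groups (only 2 supported).
#' @param linkage,metric Passed to [hier_cluster()].
#' @return Named character vector sample -> "high"/"low".
#' @export
assign_methylation_groups <- function(beta_topk, k = 2,
                                      linkage = "ward.D2",
                                      metric = "euclidean") {
  if (k != 2) stop("only k = 2 methylation groups are supported")
  m <- bm_values(beta_topk)
  if (ncol(m) < 2) stop("need at least 2 samples")
  cl <- hier_cluster(beta_topk, k = 2, linkage = linkage, metric = metric)
  mcl <- cl$clusters
  m <- impute_median_matrix(m)[, names(mcl), drop = FALSE]
  means <- tapply(colMeans(m), mcl, mean)
  if (abs(diff(means)) < 1e-12) {
    first <- tapply(names(mcl), mcl, min)
    high_cl <- names(first)[which.min(first)]
  } else {
    high_cl <- names(means)[which.max(means)]
  }
  out <- ifelse(mcl == high_cl, "high", "low")
  names(out) <- names(mcl)
  out
}

#' Kaplan-Meier product-limit survival curve
#'
#' S(t) is the product over event times t_i <= t of (1 - d_i / n_i);
#' censored subjects leave the risk set after their time. The returned
#' step function starts at S(0) = 1 and is non-increasing.
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return Data frame (time, n_risk, n_event, n_censor, survival) with a
#'   leading t = 0 row.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("empty input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1),
                    numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  rbind(data.frame(time = 0, n_risk = length(times), n_event = 0,
                   n_censor = 0, survival = 1),
        data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                   n_censor = n_censor, survival = surv))
}

#' Two-group log-rank test
#'
#' Statistic (sum over distinct event times of O1 - E1)^2 / sum V with
#' hypergeometric expectations and variances; p from chi-square with 1
#' degree of freedom. Symmetric in the group labels.
#'
#' @param times,events As in [km_curve()].
#' @param groups Two-level grouping vector.
#' @return List with `statistic`, `p.value`, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("need exactly two non-empty groups")
  stopifnot(length(times) == length(events), length(times) == length(g))
  if (!any(events == 1)) {
    warning("no events at all; p = 1")
    return(list(statistic = 0, p.value = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  ev_times <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  o_tot <- c(0, 0)
  e_tot <- c(0, 0)
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == levels(g)[1])
    e <- d * n1 / n
    o1 <- o1 + d1
    e1 <- e1 + e
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    o_tot <- o_tot + c(d1, d - d1)
    e_tot <- e_tot + c(e, d - e)
  }
  if (v <= 0) return(list(statistic = 0, p.value = 1,
                          observed = o_tot, expected = e_tot))
  stat <- (o1 - e1)^2 / v
  list(statistic = stat, p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = o_tot, expected = e_tot)
}

#' Cox proportional hazards by Newton-Raphson with Breslow ties
#'
#' Maximizes the Breslow partial likelihood; Wald standard errors come
#' from the inverse observed information. Monotone likelihood
#' (separation) is detected when a coefficient runs away and is reported
#' with the coefficient capped; non-convergence sets `converged = FALSE`
#' with a warning rather than failing silently.
#'
#' @param times,events As in [km_curve()]; at least one event.
#' @param covariates Numeric matrix (samples x covariates) without
#'   constant columns.
#' @param max_iter,tol Newton-Raphson controls.
#' @return A `cox_fit`: coefficients, hazard ratios, SEs, z, Wald p,
#'   log-likelihood, `converged`.
#' @export
cox_ph_fit <- function(times, events, covariates, max_iter = 100,
                       tol = 1e-8) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  stopifnot(length(times) == nrow(x), length(events) == nrow(x))
  if (!any(events == 1)) stop("no events; cannot fit Cox model")
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    stop("constant covariate column(s): ",
         paste(colnames(x)[const], collapse = ", "))
  }
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  beta <- numeric(p)
  cap <- 15
  converged <- FALSE
  separation <- FALSE
  loglik <- NA_real_
  imat <- NULL
  ev_times <- sort(unique(times[events == 1]))
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    eta <- eta - max(eta)               # numerical stability
    w <- exp(eta)
    U <- numeric(p)
    I <- matrix(0, p, p)
    ll <- 0
    for (t in ev_times) {
      risk <- times >= t
      dead <- times == t & events == 1
      d <- sum(dead)
      s0 <- sum(w[risk])
      s1 <- drop(crossprod(x[risk, , drop = FALSE], w[risk]))
      s2 <- crossprod(x[risk, , drop = FALSE] * w[risk],
                      x[risk, , drop = FALSE])
      xbar <- s1 / s0
      U <- U + colSums(x[dead, , drop = FALSE]) - d * xbar
      I <- I + d * (s2 / s0 - tcrossprod(xbar))
      ll <- ll + sum(eta[dead]) - d * log(s0)
    }
    step <- tryCatch(solve(I, U), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta_new <- beta + step
    if (any(abs(beta_new) > cap)) {
      separation <- TRUE
      beta <- pmin(pmax(beta_new, -cap), cap)
      loglik <- ll
      imat <- I
      warning("monotone likelihood suspected; coefficient capped at |",
              cap, "|")
      break
    }
    done <- max(abs(step)) < tol
    beta <- beta_new
    loglik <- ll
    imat <- I
    if (done) { converged <- TRUE; break }
  }
  if (!converged && !separation) {
    warning("Cox Newton-Raphson did not converge in ", max_iter,
            " iterations")
  }
  se <- tryCatch(sqrt(diag(solve(imat))), error = function(e)
    rep(NA_real_, p))
  z <- beta / se
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 hazard_ratios = stats::setNames(exp(beta), colnames(x)),
                 se = stats::setNames(se, colnames(x)), z = z,
                 p.values = 2 * stats::pnorm(-abs(z)), loglik = loglik,
                 converged = converged, separation = separation),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  df <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                   se = x$se, z = x$z, p = x$p.values)
  print(df, digits = 3)
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' Within-subtype methylation-group survival analysis
#'
#' Restricts to diagnostic samples of the given subtype (optionally
#' adding classifier-predicted members of that subtype and removing
#' listed exclusions), screens CpGs for relapse association, clusters the
#' samples into high/low methylation groups on the top CpGs, and compares
#' relapse-free and overall survival between the groups by Kaplan-Meier,
#' log-rank, and Cox regression (methylation group plus any supplied
#' covariates).
#'
#' @param beta_fs Beta matrix on the selected feature set (all samples).
#' @param sheet Sample sheet.
#' @param subtype Subtype to analyse (matched against
#'   `reported_subtype`).
#' @param include_predicted If TRUE, add `predicted` sample IDs.
#' @param predicted Character vector of sample IDs predicted into this
#'   subtype (used when `include_predicted`).
#' @param exclusions Sample IDs to drop (e.g. cluster deviants).
#' @param alpha,top_k Passed to [rank_outcome_cpgs()].
#' @param covariates Optional numeric matrix of extra Cox covariates
#'   (rownames = sample IDs).
#' @return A `survival_grouping`: selected CpGs, per-sample group, KM
#'   curves, log-rank and Cox fits per endpoint, event-free fractions.
#' @export
run_survival_stage <- function(beta_fs, sheet, subtype,
                               include_predicted = FALSE,
                               predicted = character(),
                               exclusions = character(),
                               alpha = 0.05, top_k = 50,
                               covariates = NULL) {
  m <- bm_values(beta_fs)
  diag_ids <- sheet$sample_id[sheet$timepoint == "diagnosis"]
  ids <- sheet$sample_id[sheet$reported_subtype == subtype &
                           sheet$timepoint == "diagnosis"]
  if (include_predicted) ids <- union(ids, intersect(predicted, diag_ids))
  ids <- setdiff(ids, exclusions)
  ids <- intersect(ids, colnames(m))
  sub <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  if (length(unique(sub$rfs_event)) < 2) {
    stop("subtype needs both relapse outcomes among its diagnostic samples")
  }
  bsub <- beta_matrix(m[, ids, drop = FALSE])
  ranked <- rank_outcome_cpgs(bsub, sub$rfs_event, alpha = alpha,
                              top_k = top_k)
  if (nrow(ranked) < 2) stop("fewer than 2 relapse-associated CpGs found")
  groups <- assign_methylation_groups(
    beta_matrix(m[ranked$cpg_id, ids, drop = FALSE]))
  groups <- groups[ids]

  endpoint <- function(time_col, event_col) {
    tt <- sub[[time_col]]; ee <- sub[[event_col]]
    km <- lapply(split(seq_along(ids), groups),
                 function(i) km_curve(tt[i], ee[i]))
    lr <- logrank_test(tt, ee, groups)
    xg <- cbind(group_high = as.numeric(groups == "high"))
    rownames(xg) <- ids
    if (!is.null(covariates)) {
      xg <- cbind(xg, covariates[ids, , drop = FALSE])
    }
    cox <- tryCatch(cox_ph_fit(tt, ee, xg),
                    error = function(e) { warning(conditionMessage(e)); NULL })
    event_free <- vapply(split(ee, groups),
                         function(e) mean(e == 0), numeric(1))
    list(km = km, logrank = lr, cox = cox, event_free = event_free)
  }
  structure(list(subtype = subtype, sample_ids = ids,
                 selected_cpgs = ranked, groups = groups,
                 rfs = endpoint("rfs_time", "rfs_event"),
                 os = endpoint("os_time", "os_event")),
            class = "survival_grouping")
}

#' @export
print.survival_grouping <- function(x, ...) {
  cat("Survival grouping for subtype", x$subtype, "-",
      length(x$sample_ids), "samples,", nrow(x$selected_cpgs),
      "selected CpGs\n")
  print(table(x$groups))
  cat(sprintf("  RFS log-rank p = %.4g; OS log-rank p = %.4g\n",
              x$rfs$logrank$p.value, x$os$logrank$p.value))
  invisible(x)
}
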