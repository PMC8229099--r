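#' Mann-Whitney U test (two-sided)
#'
#' The statistic is U for the first group (number of (x, y) pairs with
#' x > y, counting ties as 1/2). With `mode = "auto"` the exact
#' distribution is enumerated when n_x + n_y <= 12 and there are no ties;
#' otherwise a normal approximation with tie and continuity correction is
#' used. `U_x + U_y = n_x * n_y` always holds.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode "auto", "exact" or "normal".
#' @return List with `statistic` (U of `x`) and `p.value`.
#' @export
mannwhitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = (nx + ny <= 12) && !ties)
  if (use_exact && ties) stop("exact mode requires untied data")
  if (use_exact) {
    ## enumerate all rank arrangements of x among the nx + ny positions
    combos <- utils::combn(nx + ny, nx)
    us <- colSums(combos) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p.value = 1))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u, p.value = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' adj_i = min over j >= i (in the sorted order) of m * p_(j) / j, capped
#' at 1 and returned in the original input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m <= 1) return(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' One-vs-rest differential methylation per subtype
#'
#' For every subtype with at least `min_group` samples, each CpG is tested
#' by Mann-Whitney against all remaining samples (missing values dropped
#' per CpG), p-values are BH-adjusted within the subtype, and CpGs with
#' adjusted p < `alpha` form the significant set. Subtypes below
#' `min_group` are skipped with a warning (small cytogenetic groups do not
#' support subtype-specific calls).
#'
#' @param beta_fs Beta matrix (typically restricted to selected features).
#' @param labels Subtype per sample.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_group Minimum subtype size (default 3).
#' @return A `dm_result`: `table` (long data frame: subtype, cpg_id, U,
#'   p, adj_p, delta_beta, significant), `significant` (named list),
#'   `skipped`.
#' @export
one_vs_rest_dm <- function(beta_fs, labels, alpha = 0.05, min_group = 3) {
  m <- bm_values(beta_fs)
  y <- as.character(labels)
  stopifnot(ncol(m) == length(y))
  subtypes <- sort(unique(y))
  if (length(subtypes) < 2) stop("need at least two classes")
  sizes <- table(y)
  skipped <- subtypes[sizes[subtypes] < min_group]
  if (length(skipped)) {
    warning("subtype(s) below min_group skipped: ",
            paste(skipped, collapse = ", "))
  }
  rows <- list()
  for (s in setdiff(subtypes, skipped)) {
    in_s <- y == s
    res <- apply(m, 1, function(v) {
      xs <- v[in_s & !is.na(v)]
      ys <- v[!in_s & !is.na(v)]
      if (!length(xs) || !length(ys)) return(c(NA_real_, 1, NA_real_))
      mw <- mannwhitney_u(xs, ys, mode = "normal")
      c(mw$statistic, mw$p.value, mean(xs) - mean(ys))
    })
    adj <- bh_adjust(res[2, ])
    rows[[s]] <- data.frame(
      subtype = s, cpg_id = rownames(m), U = res[1, ], p = res[2, ],
      adj_p = adj, delta_beta = res[3, ], significant = adj < alpha,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sig <- lapply(split(tab, tab$subtype),
                function(d) d$cpg_id[d$significant])
  structure(list(table = tab, significant = sig, skipped = skipped,
                 alpha = alpha),
            class = "dm_result")
}

#' Subtype-unique significant CpGs
#'
#' The unique set of subtype s is its significant set minus the union of
#' every other subtype's significant set; unique sets are therefore
#' pairwise disjoint.
#'
#' @param result A `dm_result` from [one_vs_rest_dm()].
#' @return Named list of unique CpG vectors per subtype.
#' @export
unique_cpgs <- function(result) {
  sig <- result$significant
  out <- lapply(names(sig), function(s) {
    setdiff(sig[[s]], unlist(sig[names(sig) != s], use.names = FALSE))
  })
  names(out) <- names(sig)
  out
}

#' Write a dm_result as long-format TSV
#' @param result A `dm_result`.
#' @param path Output file path.
#' @export
write_dm_result <- function(result, path) {
  tab <- result$table
  uni <- unique_cpgs(result)
  tab$unique <- mapply(function(s, cg) cg %in% uni[[s]],
                       tab$subtype, tab$cpg_id)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
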