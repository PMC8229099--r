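# Shared fixtures and small oracles used across test files.

# beta matrix with named dimensions from a plain matrix
bm <- function(values, cpgs = NULL, samples = NULL) {
  if (is.null(cpgs)) cpgs <- sprintf("cg%05d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  beta_matrix(values, cpg_ids = cpgs, sample_ids = samples)
}

# two well-separated classes: class signature shifts on disjoint CpG blocks
separable_fixture <- function(n_per_class = 15, n_cpgs = 60, delta = 0.4,
                              noise = 0.03, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  base <- stats::runif(n_cpgs, 0.2, 0.5)
  m <- matrix(base, n_cpgs, n)
  m[1:10, seq_len(n_per_class)] <- m[1:10, seq_len(n_per_class)] + delta
  m[11:20, n_per_class + seq_len(n_per_class)] <-
    m[11:20, n_per_class + seq_len(n_per_class)] + delta
  m <- pmin(pmax(m + stats::rnorm(length(m), sd = noise), 0), 1)
  list(beta = bm(m), labels = rep(c("g1", "g2"), each = n_per_class))
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# brute-force log-rank statistic, summing over each distinct event time
logrank_brute <- function(times, events, groups) {
  g <- factor(groups)
  ev <- sort(unique(times[events == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in ev) {
    risk <- times >= t
    n <- sum(risk); n1 <- sum(risk & g == levels(g)[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == levels(g)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o1 - e1)^2 / v
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
signed_rank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}
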