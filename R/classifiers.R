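## Binary probabilistic classifier families and the one-vs-rest wrapper.
## Every family exposes fit(x, y01, params, seed) -> model and
## prob(model, xnew) -> P(class = 1). x is samples x features, fully
## imputed. Families with no positive (or no negative) training examples
## are replaced by a constant model in the one-vs-rest layer.

clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# When p >> n, linear-input models (linear SVM, MLP first layer) act on X
# only through the n-dimensional row space; training on Z = (X - center) V
# from a thin SVD is an exact reparametrization (minimal-norm weights have
# equal L2 norm) and cuts per-epoch cost by ~p/n.
compress_train <- function(x) {
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  if (ncol(xc) <= nrow(xc)) {
    return(list(z = xc, V = NULL, center = center))
  }
  sv <- svd(xc, nu = 0)
  keep <- which(sv$d > sv$d[1] * 1e-8)
  V <- sv$v[, keep, drop = FALSE]
  list(z = xc %*% V, V = V, center = center)
}
compress_apply <- function(comp, xnew) {
  xc <- sweep(xnew, 2, comp$center)
  if (is.null(comp$V)) xc else xc %*% comp$V
}

fit_nearest_centroid <- function(x, y01, params, seed) {
  mu1 <- colMeans(x[y01 == 1, , drop = FALSE])
  mu0 <- colMeans(x[y01 == 0, , drop = FALSE])
  ## pooled per-feature residual variance -> Gaussian (LDA-like) posterior
  res <- x - rbind(mu0, mu1)[y01 + 1, , drop = FALSE]
  list(mu1 = mu1, mu0 = mu0, sig2 = max(mean(res^2), 1e-6))
}
prob_nearest_centroid <- function(model, xnew) {
  d1 <- colSums((t(xnew) - model$mu1)^2)
  d0 <- colSums((t(xnew) - model$mu0)^2)
  stats::plogis((d0 - d1) / (2 * model$sig2))
}

fit_knn <- function(x, y01, params, seed) {
  list(x = x, y = y01, k = min(params$k, nrow(x)))
}
prob_knn <- function(model, xnew) {
  idx <- FNN::knnx.index(model$x, xnew, k = model$k)
  rowMeans(matrix(model$y[idx], nrow(xnew), model$k))
}

fit_logistic <- function(x, y01, params, seed) {
  fit <- tryCatch(
    glmnet::glmnet(x, factor(y01, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = params$lambda, standardize = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(list(constant = mean(y01)))
  list(glmnet = fit)
}
prob_logistic <- function(model, xnew) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(xnew)))
  as.numeric(stats::predict(model$glmnet, xnew, type = "response"))
}

# linear SVM, squared hinge, trained by L-BFGS on the primal in the
# row-space basis (exact for the minimal-norm solution)
fit_svm_linear <- function(x, y01, params, seed) {
  comp <- compress_train(x)
  x <- comp$z
  z <- 2 * y01 - 1
  p <- ncol(x)
  n <- nrow(x)
  C <- params$cost
  obj <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    f <- drop(x %*% w) + b
    s <- pmax(0, 1 - z * f)
    0.5 * sum(w^2) + C * sum(s^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    f <- drop(x %*% w) + b
    s <- pmax(0, 1 - z * f)
    gz <- -2 * C * s * z
    c(w + drop(crossprod(x, gz)), sum(gz))
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 60))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1], comp = comp)
}
prob_svm_linear <- function(model, xnew) {
  z <- compress_apply(model$comp, xnew)
  stats::plogis(drop(z %*% model$w) + model$b)
}

fit_naive_bayes <- function(x, y01, params, seed) {
  eps <- params$var_smoothing * max(apply(x, 2, stats::var), 1e-9)
  stat <- function(rows) {
    xs <- x[rows, , drop = FALSE]
    list(mu = colMeans(xs),
         v = apply(xs, 2, stats::var) + eps,
         logprior = log(length(which(rows)) / nrow(x)))
  }
  s1 <- stat(y01 == 1); s0 <- stat(y01 == 0)
  s1$v[is.na(s1$v)] <- eps; s0$v[is.na(s0$v)] <- eps
  list(s1 = s1, s0 = s0)
}
prob_naive_bayes <- function(model, xnew) {
  ll <- function(s) {
    colSums(-0.5 * (t(xnew) - s$mu)^2 / s$v - 0.5 * log(2 * pi * s$v)) +
      s$logprior
  }
  stats::plogis(ll(model$s1) - ll(model$s0))
}

fit_decision_tree <- function(x, y01, params, seed) {
  list(tree = cpp_tree_fit(x, y01, max_depth = params$max_depth,
                           min_split = 2L, mtry = ncol(x), seed = seed))
}
prob_decision_tree <- function(model, xnew) {
  clip01(cpp_tree_predict(model$tree, xnew), 0)
}

fit_random_forest <- function(x, y01, params, seed) {
  mtry <- max(1L, floor(sqrt(ncol(x)) * params$mtry_factor))
  list(forest = cpp_rf_fit(x, y01, n_trees = 80L,
                           max_depth = 20L, min_split = 2L,
                           mtry = mtry, seed = seed))
}
prob_random_forest <- function(model, xnew) {
  clip01(cpp_rf_predict(model$forest, xnew), 0)
}

fit_gradient_boosting <- function(x, y01, params, seed) {
  list(gbm = cpp_gbm_fit(x, y01, n_rounds = params$n_rounds,
                         max_depth = 3L, shrinkage = 0.2, seed = seed))
}
prob_gradient_boosting <- function(model, xnew) {
  cpp_gbm_predict(model$gbm, xnew)
}

# one-hidden-layer perceptron (tanh), Adam, early stopping on a held-out
# fifth of the training data when both classes allow it
fit_mlp <- function(x, y01, params, seed,
                    epochs = 60, lr = 0.02, l2 = 1e-4, patience = 8) {
  set.seed(seed)
  h <- params$hidden
  comp <- compress_train(x)
  xs <- comp$z
  p <- ncol(xs)
  n <- nrow(xs)
  val <- integer(0)
  if (n >= 15 && min(sum(y01 == 1), sum(y01 == 0)) >= 5) {
    val <- sample(n, max(3, floor(n / 5)))
    if (length(unique(y01[-val])) < 2) val <- integer(0)
  }
  tr <- if (length(val)) setdiff(seq_len(n), val) else seq_len(n)
  W1 <- matrix(stats::rnorm(p * h, sd = sqrt(1 / p)), p, h)
  b1 <- numeric(h); w2 <- stats::rnorm(h, sd = sqrt(1 / h)); b2 <- 0
  mom <- lapply(list(W1, b1, w2, b2), function(z) z * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  forward <- function(xm) {
    H <- tanh(sweep(xm %*% W1, 2, b1, "+"))
    list(H = H, f = drop(H %*% w2) + b2)
  }
  loss_of <- function(f, y) {
    pr <- clip01(stats::plogis(f))
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  best_loss <- Inf; bad <- 0; t_step <- 0
  xt <- xs[tr, , drop = FALSE]; yt <- y01[tr]
  for (epoch in seq_len(epochs)) {
    fw <- forward(xt)
    pr <- stats::plogis(fw$f)
    dF <- (pr - yt) / length(yt)
    gW2 <- drop(crossprod(fw$H, dF)) + 2 * l2 * w2
    gB2 <- sum(dF)
    dH <- outer(dF, w2) * (1 - fw$H^2)
    gW1 <- crossprod(xt, dH) + 2 * l2 * W1
    gB1 <- colSums(dH)
    grads <- list(gW1, gB1, gW2, gB2)
    t_step <- t_step + 1
    pars <- list(W1, b1, w2, b2)
    for (i in 1:4) {
      mom[[i]] <- beta1 * mom[[i]] + (1 - beta1) * grads[[i]]
      vel[[i]] <- beta2 * vel[[i]] + (1 - beta2) * grads[[i]]^2
      mhat <- mom[[i]] / (1 - beta1^t_step)
      vhat <- vel[[i]] / (1 - beta2^t_step)
      pars[[i]] <- pars[[i]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
    W1 <- pars[[1]]; b1 <- pars[[2]]; w2 <- pars[[3]]; b2 <- pars[[4]]
    if (length(val)) {
      vloss <- loss_of(forward(xs[val, , drop = FALSE])$f, y01[val])
      if (vloss < best_loss - 1e-6) {
        best_loss <- vloss
        best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
        bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= patience) break
      }
    }
  }
  if (!length(val)) best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  c(best, list(comp = comp))
}
# Batched one-vs-rest MLP: the K independent binary networks are trained
# in one loop using block matrices (W2 is block-diagonal, so gradients
# never mix classes). This is K independent nets with a shared epoch
# schedule and validation split, at ~1/K of the R-level overhead.
mlp_fit_multi <- function(x, y01_mat, params, seed,
                          epochs = 60, lr = 0.02, l2 = 1e-4, patience = 8) {
  set.seed(seed)
  h <- params$hidden
  K <- ncol(y01_mat)
  comp <- compress_train(x)
  xs <- comp$z
  p <- ncol(xs)
  n <- nrow(xs)
  val <- integer(0)
  if (n >= 15) val <- sample(n, max(3, floor(n / 5)))
  if (length(val) && any(colSums(y01_mat[-val, , drop = FALSE]) == 0)) {
    val <- integer(0)
  }
  tr <- if (length(val)) setdiff(seq_len(n), val) else seq_len(n)
  Kh <- K * h
  W1 <- matrix(stats::rnorm(p * Kh, sd = sqrt(1 / p)), p, Kh)
  b1 <- numeric(Kh)
  mask <- matrix(0, Kh, K)
  for (k in seq_len(K)) mask[(k - 1) * h + seq_len(h), k] <- 1
  W2 <- matrix(stats::rnorm(Kh, sd = sqrt(1 / h)), Kh, K) * mask
  b2 <- numeric(K)
  mom <- lapply(list(W1, b1, W2, b2), function(z) z * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  fwd <- function(xm) {
    H <- tanh(sweep(xm %*% W1, 2, b1, "+"))
    list(H = H, F = sweep(H %*% W2, 2, b2, "+"))
  }
  loss_of <- function(Fm, Y) {
    P <- clip01(stats::plogis(Fm))
    -mean(Y * log(P) + (1 - Y) * log(1 - P))
  }
  xt <- xs[tr, , drop = FALSE]; Yt <- y01_mat[tr, , drop = FALSE]
  best <- list(W1, b1, W2, b2)
  best_loss <- Inf; bad <- 0; t_step <- 0
  for (epoch in seq_len(epochs)) {
    f <- fwd(xt)
    P <- stats::plogis(f$F)
    dF <- (P - Yt) / nrow(Yt)
    gW2 <- (crossprod(f$H, dF) + 2 * l2 * W2) * mask
    gB2 <- colSums(dF)
    dH <- (dF %*% t(W2)) * (1 - f$H^2)
    gW1 <- crossprod(xt, dH) + 2 * l2 * W1
    gB1 <- colSums(dH)
    grads <- list(gW1, gB1, gW2, gB2)
    pars <- list(W1, b1, W2, b2)
    t_step <- t_step + 1
    for (i in 1:4) {
      mom[[i]] <- beta1 * mom[[i]] + (1 - beta1) * grads[[i]]
      vel[[i]] <- beta2 * vel[[i]] + (1 - beta2) * grads[[i]]^2
      mhat <- mom[[i]] / (1 - beta1^t_step)
      vhat <- vel[[i]] / (1 - beta2^t_step)
      pars[[i]] <- pars[[i]] - lr * mhat / (sqrt(vhat) + eps)
    }
    W1 <- pars[[1]]; b1 <- pars[[2]]; W2 <- pars[[3]] * mask; b2 <- pars[[4]]
    if (length(val)) {
      vloss <- loss_of(fwd(xs[val, , drop = FALSE])$F,
                       y01_mat[val, , drop = FALSE])
      if (vloss < best_loss - 1e-6) {
        best_loss <- vloss
        best <- list(W1, b1, W2, b2)
        bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= patience) break
      }
    }
  }
  if (!length(val)) best <- list(W1, b1, W2, b2)
  lapply(seq_len(K), function(k) {
    cols <- (k - 1) * h + seq_len(h)
    list(W1 = best[[1]][, cols, drop = FALSE], b1 = best[[2]][cols],
         w2 = best[[3]][cols, k], b2 = best[[4]][k], comp = comp)
  })
}

prob_mlp <- function(model, xnew) {
  xs <- compress_apply(model$comp, xnew)
  H <- tanh(sweep(xs %*% model$W1, 2, model$b1, "+"))
  stats::plogis(drop(H %*% model$w2) + model$b2)
}

classifier_families <- function() {
  list(
    "nearest centroid" = list(
      fit = fit_nearest_centroid, prob = prob_nearest_centroid,
      grid = list(list())),
    "naive Bayes" = list(
      fit = fit_naive_bayes, prob = prob_naive_bayes,
      grid = lapply(c(1e-9, 1e-6, 1e-3),
                    function(v) list(var_smoothing = v))),
    "k-nearest neighbors" = list(
      fit = fit_knn, prob = prob_knn,
      grid = lapply(c(3L, 5L, 7L), function(k) list(k = k))),
    "logistic regression" = list(
      fit = fit_logistic, prob = prob_logistic,
      grid = lapply(c(1, 0.1, 0.01), function(l) list(lambda = l))),
    "support vector machine" = list(
      fit = fit_svm_linear, prob = prob_svm_linear,
      grid = lapply(c(0.1, 1, 10), function(C) list(cost = C))),
    "decision tree" = list(
      fit = fit_decision_tree, prob = prob_decision_tree,
      grid = lapply(c(3L, 5L, 10L), function(d) list(max_depth = d))),
    "random forest" = list(
      fit = fit_random_forest, prob = prob_random_forest,
      grid = lapply(c(1, 2), function(f) list(mtry_factor = f))),
    "gradient boosting" = list(
      fit = fit_gradient_boosting, prob = prob_gradient_boosting,
      grid = lapply(c(40L, 80L), function(r) list(n_rounds = r))),
    "multilayer perceptron" = list(
      fit = fit_mlp, prob = prob_mlp, fit_multi = mlp_fit_multi,
      grid = lapply(c(32L, 64L, 128L), function(h) list(hidden = h)))
  )
}

#' Describe a classifier family and its hyperparameter grid
#'
#' @param family One of: nearest centroid, naive Bayes, k-nearest
#'   neighbors, logistic regression, support vector machine, decision
#'   tree, random forest, gradient boosting, multilayer perceptron.
#' @param grid Optional list of named hyperparameter combinations; the
#'   family default grid is used when omitted. Must be non-empty.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family, grid = NULL) {
  fams <- classifier_families()
  if (!family %in% names(fams)) {
    stop("unknown model family: ", family, "; expected one of ",
         paste(names(fams), collapse = ", "))
  }
  if (is.null(grid)) grid <- fams[[family]]$grid
  if (!length(grid)) stop("hyperparameter grid must be non-empty")
  structure(list(family = family, grid = grid), class = "model_spec")
}

#' Default bank of nine classifier specifications
#'
#' Eight classical families plus a one-hidden-layer perceptron standing in
#' for the neural network (widths 32/64/128, early stopping).
#'
#' @return Named list of [model_spec()] objects.
#' @export
default_model_specs <- function() {
  fams <- names(classifier_families())
  stats::setNames(lapply(fams, model_spec), fams)
}

## ---- one-vs-rest wrapper ----

ovr_fit <- function(x, y, family_name, params, seed) {
  fam <- classifier_families()[[family_name]]
  classes <- levels(y)
  counts <- table(factor(y, levels = classes))
  models <- vector("list", length(classes))
  names(models) <- classes
  y01_mat <- vapply(classes, function(cl) as.numeric(y == cl),
                    numeric(length(y)))
  y01_mat <- matrix(y01_mat, length(y), length(classes))
  fit_cols <- which(colSums(y01_mat) > 0 & colSums(y01_mat) < length(y))
  if (!is.null(fam$fit_multi) && length(fit_cols)) {
    fitted <- fam$fit_multi(x, y01_mat[, fit_cols, drop = FALSE], params,
                            seed = seed)
    models[fit_cols] <- fitted
  } else {
    for (i in fit_cols) {
      models[[i]] <- fam$fit(x, y01_mat[, i], params, seed = seed + i)
    }
  }
  for (i in setdiff(seq_along(classes), fit_cols)) {
    models[[i]] <- list(.constant = mean(y01_mat[, i]))
  }
  structure(list(family = family_name, params = params, models = models,
                 classes = classes, counts = as.numeric(counts)),
            class = "ovr_fit")
}

ovr_prob <- function(fit, xnew) {
  fam <- classifier_families()[[fit$family]]
  pr <- vapply(fit$models, function(m) {
    if (!is.null(m$.constant)) rep(m$.constant, nrow(xnew))
    else fam$prob(m, xnew)
  }, numeric(nrow(xnew)))
  pr <- matrix(pr, nrow(xnew), length(fit$classes),
               dimnames = list(rownames(xnew), fit$classes))
  pr[!is.finite(pr)] <- 0
  pr <- pmin(pmax(pr, 0), 1)
  rs <- rowSums(pr)
  zero <- rs <= 0
  pr[zero, ] <- 1 / ncol(pr)
  pr[!zero, ] <- pr[!zero, , drop = FALSE] / rs[!zero]
  pr
}

# argmax with ties broken by larger training class, then class name order
ovr_label <- function(fit, prob) {
  apply(prob, 1, function(p) {
    cand <- which(p >= max(p) - 1e-12)
    cand <- cand[order(-fit$counts[cand], fit$classes[cand])]
    fit$classes[cand[1]]
  })
}
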