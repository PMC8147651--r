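# Independent oracles used across the suite. These deliberately avoid the
# package's solver paths: dense Kronecker-expanded linear solves, triple-loop
# contractions, and O(n^2) metric counts.

# Solve the defining equation literally: vec(Y) = (K3+l3*I) x (K2+l2*I) x
# (K1+l1*I) vec(A) with mode-1 index fastest (R array order).
dense_solve_threestep <- function(y, kd, ke, lambda) {
  k1 <- kd + diag(lambda[1], nrow(kd))
  k2 <- kd + diag(lambda[2], nrow(kd))
  k3 <- ke + diag(lambda[3], nrow(ke))
  m <- kronecker(k3, kronecker(k2, k1))
  array(solve(m, as.vector(y)), dim = dim(y))
}

# Triple-loop evaluation of the prediction function at one query.
naive_predict <- function(a, v1, v2, v3) {
  d <- dim(a)
  out <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out <- out + a[i, j, k] * v1[i] * v2[j] * v3[k]
  out
}

# Exhaustive pairwise-comparison AUC-ROC (ties count one half).
auc_roc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Precision-at-rank average precision for tie-free scores.
auc_pr_rankwalk <- function(scores, labels) {
  stopifnot(!anyDuplicated(scores))
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]
  ranks <- which(l == 1)
  if (!length(ranks)) return(NA_real_)
  mean(vapply(ranks, function(r) sum(l[1:r]) / r, numeric(1)))
}

# Random symmetric binary label tensor as a validated triplet tensor.
rand_tensor <- function(n_drugs, n_effects, p = 0.2) {
  a <- array(0, c(n_drugs, n_drugs, n_effects))
  for (k in seq_len(n_effects)) {
    m <- matrix(0, n_drugs, n_drugs)
    up <- upper.tri(m)
    m[up] <- rbinom(sum(up), 1, p)
    a[, , k] <- m + t(m)
  }
  as_triplet_tensor(a)
}

rand_psd <- function(n, unit_diag = FALSE) {
  x <- matrix(rnorm(n * (n + 2)), n)
  k <- tcrossprod(x) / (n + 2)
  if (unit_diag) k <- cov2cor(k)
  k
}

# Explicit per-fold retrain, the holdout oracle: builds the fold's training
# inputs from fold_roles() only, solves the dense Kronecker system, and
# scores the fold's test triplets by direct contraction.
naive_fold_retrain <- function(x, kd, plan, fold, lambda,
                               effect_method = "cosine") {
  r <- fold_roles(plan, fold)
  y <- as.array(x)
  ke <- effect_kernel(x, train_pairs = r$kernel_pairs, method = effect_method)
  if (plan$scheme %in% c("dde", "dd_e")) {
    ytr <- y
    ytr[r$test[, c("i", "j", "k"), drop = FALSE]] <- 0
    ytr[r$test[, c("j", "i", "k"), drop = FALSE]] <- 0
    a <- dense_solve_threestep(ytr, kd, ke, lambda)
    f1 <- trikrr:::tmode(trikrr:::tmode(trikrr:::tmode(a, kd, 1), kd, 2), ke, 3)
    s <- (f1[r$test[, c("i", "j", "k"), drop = FALSE]] +
            f1[r$test[, c("j", "i", "k"), drop = FALSE]]) / 2
  } else {
    tr <- r$train_drugs
    a <- dense_solve_threestep(y[tr, tr, , drop = FALSE],
                               kd[tr, tr, drop = FALSE], ke, lambda)
    s <- numeric(nrow(r$test))
    for (q in seq_len(nrow(r$test))) {
      i <- r$test[q, "i"]; j <- r$test[q, "j"]; k <- r$test[q, "k"]
      if (plan$scheme == "d_de") {
        s[q] <- naive_predict(a, kd[i, tr], kd[j, tr], ke[k, ])
      } else {
        s[q] <- (naive_predict(a, kd[i, tr], kd[j, tr], ke[k, ]) +
                   naive_predict(a, kd[j, tr], kd[i, tr], ke[k, ])) / 2
      }
    }
  }
  data.frame(i = r$test[, "i"], j = r$test[, "j"], k = r$test[, "k"],
             fold = fold, score = s)
}

# Pool oracle fold scores the same way the package does (mean per canonical
# triplet) but with straightforward aggregate().
naive_pooled <- function(x, kd, plan, lambda, effect_method = "cosine") {
  rows <- do.call(rbind, lapply(seq_len(plan$n_folds), function(f)
    naive_fold_retrain(x, kd, plan, f, lambda, effect_method)))
  rows$ci <- pmin(rows$i, rows$j)
  rows$cj <- pmax(rows$i, rows$j)
  stats::aggregate(score ~ ci + cj + k, data = rows, FUN = mean)
}

# Minimal cv_predictions stand-in for detection tests.
fake_predictions <- function(scores_df, scheme = "dde", n_drugs, n_effects) {
  structure(list(scores = scores_df, unpooled = scores_df, scheme = scheme,
                 n_folds = 2L, seed = 0L, lambda = c(1, 1, 1),
                 n_drugs = n_drugs, n_effects = n_effects),
            class = "cv_predictions")
}
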