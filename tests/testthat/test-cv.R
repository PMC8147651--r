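test_that("cell-level schemes partition all canonical triplets across folds", {
  set.seed(20)
  y <- rand_tensor(9, 3, p = 0.3)
  for (sch in c("dde", "dd_e")) {
    plan <- make_folds(sch, y, n_folds = if (sch == "dde") 4 else 3, seed = 5)
    seen <- matrix(0, trikrr:::n_pairs(9), 3)
    for (f in seq_len(plan$n_folds)) {
      r <- fold_roles(plan, f)
      idx <- cbind(trikrr:::pair_id(r$test[, "i"], r$test[, "j"], 9),
                   r$test[, "k"])
      seen[idx] <- seen[idx] + 1
    }
    expect_true(all(seen == 1))
  }
})

test_that("drug-level schemes exclude test drugs from all training inputs", {
  set.seed(22)
  y <- rand_tensor(9, 2, p = 0.3)
  plan <- make_folds("d_de", y, n_folds = 3, seed = 6)
  for (f in 1:3) {
    r <- fold_roles(plan, f)
    expect_length(intersect(r$test_drugs, r$train_drugs), 0)
    # no training triplet (pair within train drugs) contains a test drug
    expect_false(any(r$kernel_pairs %in% r$test_drugs))
    # test triplets pair one new drug with one training drug
    expect_true(all(r$test[, "i"] %in% r$test_drugs))
    expect_true(all(r$test[, "j"] %in% r$train_drugs))
    # both-test pairs are discarded
    expect_true(all(r$discard[, "i"] %in% r$test_drugs &
                      r$discard[, "j"] %in% r$test_drugs))
  }
  plan2 <- make_folds("d_d_e", y, n_folds = 3, seed = 6)
  for (f in 1:3) {
    r <- fold_roles(plan2, f)
    expect_true(all(r$test[, c("i", "j")] %in% r$test_drugs))
    # mixed pairs discarded
    expect_true(all(xor(r$discard[, "i"] %in% r$test_drugs,
                        r$discard[, "j"] %in% r$test_drugs)))
  }
  expect_error(make_folds("d_de", y, n_folds = 20, seed = 1), "more folds")
})

test_that("held-out pairs carry all their effects into the test set", {
  set.seed(23)
  y <- rand_tensor(8, 4, p = 0.3)
  plan <- make_folds("dd_e", y, n_folds = 4, seed = 2)
  for (f in 1:4) {
    r <- fold_roles(plan, f)
    tab <- table(trikrr:::pair_id(r$test[, "i"], r$test[, "j"], 8))
    expect_true(all(tab == 4))      # every test pair appears with all effects
    ytr <- trikrr:::training_tensor(as.array(y), r)
    expect_equal(sum(ytr[r$test[, c("i", "j", "k")]]), 0)
  }
})

test_that("contamination audits pass on randomized instances of all schemes", {
  set.seed(24)
  for (nd in c(12, 30, 50)) {
    y <- rand_tensor(nd, 4, p = 0.1)
    for (sch in c("dde", "dd_e", "d_de", "d_d_e")) {
      plan <- make_folds(sch, y, n_folds = 4, seed = nd)
      expect_true(audit_folds(plan, y))
    }
  }
})

test_that("holdout predictions equal explicit per-fold retraining (all schemes)", {
  set.seed(25)
  y <- rand_tensor(8, 3, p = 0.3)
  sim_feats <- matrix(rbinom(8 * 16, 1, 0.4), 8, 16)
  kd <- gaussian_kernel(sim_feats)
  lam <- c(0.05, 0.02, 0.3)
  for (sch in c("dde", "dd_e", "d_de", "d_d_e")) {
    plan <- make_folds(sch, y, n_folds = if (sch == "dde") 2 else 4,
                       seed = 30)
    got <- suppressWarnings(cv_predict(y, plan, lam, kd = kd))
    ref <- suppressWarnings(naive_pooled(y, kd, plan, lam))
    m <- merge(got$scores, ref, by.x = c("i", "j", "k"),
               by.y = c("ci", "cj", "k"))
    expect_equal(nrow(m), nrow(got$scores))
    expect_lt(max(abs(m$score.x - m$score.y)), 1e-8)
  }
})

test_that("every pooled test triplet has exactly one score", {
  set.seed(26)
  y <- rand_tensor(10, 3, p = 0.2)
  feats <- matrix(rbinom(10 * 16, 1, 0.4), 10, 16)
  for (sch in c("dde", "dd_e", "d_de", "d_d_e")) {
    plan <- make_folds(sch, y, n_folds = 2, seed = 3)
    cp <- suppressWarnings(cv_predict(y, plan, c(0.1, 0.1, 0.1),
                                      features = feats))
    key <- with(cp$scores, paste(i, j, k))
    expect_false(any(duplicated(key)))
    expect_true(all(cp$scores$i < cp$scores$j))
  }
})

test_that("extreme regularization drives out-of-fold predictions to zero", {
  set.seed(27)
  y <- rand_tensor(8, 3, p = 0.3)
  feats <- matrix(rbinom(8 * 16, 1, 0.4), 8, 16)
  plan <- make_folds("dd_e", y, n_folds = 4, seed = 1)
  cp <- suppressWarnings(cv_predict(y, plan, c(1e9, 1e9, 1e9),
                                    features = feats))
  expect_lt(max(abs(cp$scores$score)), 1e-6)
})

test_that("a lambda grid shares fold contexts without changing results", {
  set.seed(28)
  y <- rand_tensor(9, 3, p = 0.25)
  feats <- matrix(rbinom(9 * 16, 1, 0.4), 9, 16)
  plan <- make_folds("d_de", y, n_folds = 3, seed = 8)
  lams <- list(c(0.1, 0.01, 0.5), c(1, 1, 1))
  both <- suppressWarnings(cv_predict(y, plan, lams, features = feats))
  for (t in 1:2) {
    single <- suppressWarnings(cv_predict(y, plan, lams[[t]],
                                          features = feats))
    expect_equal(both[[t]]$scores, single$scores, tolerance = 1e-12)
  }
})

test_that("block deflation reproduces refitting a mode-wise ridge without S", {
  set.seed(29)
  k <- rand_psd(10)
  yv <- rnorm(10)
  lam <- 0.4
  h <- hat_matrix(k, lam)
  s <- c(2, 5, 9)
  got <- block_deflate(h, yv, s)
  # oracle: kernel ridge refit on the remaining indices, predict at s
  r <- setdiff(1:10, s)
  alpha <- solve(k[r, r] + diag(lam, length(r)), yv[r])
  expect_equal(got, drop(k[s, r] %*% alpha), tolerance = 1e-10)
  # held-out labels do not influence the corrected predictions
  y2 <- yv
  y2[s] <- rnorm(3)
  expect_equal(block_deflate(h, y2, s), got, tolerance = 1e-10)
  # single index reduces to the classical leave-one-out shortcut
  i <- 4L
  yhat <- drop(h %*% yv)
  expect_equal(block_deflate(h, yv, i),
               (yhat[i] - h[i, i] * yv[i]) / (1 - h[i, i]), tolerance = 1e-12)
  # identity-kernel LOO carries no cross-information
  h_id <- hat_matrix(diag(6), 1)
  expect_equal(block_deflate(h_id, rnorm(6), 3L), 0)
})
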