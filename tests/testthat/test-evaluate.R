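test_that("AUC-ROC matches exhaustive pairwise comparison and its analytic cases", {
  expect_equal(auc_roc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(auc_roc(rep(2, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  expect_true(is.na(auc_roc(1:4, rep(1, 4))))
  set.seed(31)
  s <- round(rnorm(200), 1)          # induce ties
  l <- rbinom(200, 1, 0.3)
  expect_equal(auc_roc(s, l), auc_roc_pairwise(s, l), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(auc_roc(exp(3 * s), l), auc_roc(s, l))
})

test_that("AUC-PR matches the precision-at-rank walk", {
  expect_equal(auc_pr(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_true(is.na(auc_pr(1:4, rep(0, 4))))
  set.seed(32)
  for (rep in 1:5) {
    s <- rnorm(50)
    l <- rbinom(50, 1, 0.3)
    if (sum(l) == 0) next
    expect_equal(auc_pr(s, l), auc_pr_rankwalk(s, l), tolerance = 1e-12)
  }
})

test_that("no-skill AUC-PR equals the positive prevalence", {
  set.seed(33)
  n <- 1e5
  l <- rbinom(n, 1, 0.02)
  vals <- replicate(5, auc_pr(runif(n), l))
  expect_lt(abs(mean(vals) - 0.02), 0.003)
})

test_that("macro evaluation reduces to per-unit loops and skips single-class units", {
  set.seed(34)
  n_pair <- 20; n_eff <- 6
  df <- expand.grid(p = seq_len(n_pair), k = seq_len(n_eff))
  df$i <- df$p
  df$j <- df$p + n_pair              # distinct pair per row-block
  df$label <- rbinom(nrow(df), 1, 0.3)
  df$score <- rnorm(nrow(df))
  edd <- macro_evaluate(df, "Edd", "auc_roc")
  ref <- sapply(seq_len(n_eff), function(k)
    auc_roc_pairwise(df$score[df$k == k], df$label[df$k == k]))
  expect_equal(unname(edd$per_unit[order(as.numeric(names(edd$per_unit)))]),
               ref, tolerance = 1e-12)
  expect_equal(edd$mean, mean(ref, na.rm = TRUE))
  ee <- macro_evaluate(df, "Ee", "auc_pr")
  refp <- sapply(seq_len(n_pair), function(p) {
    ix <- df$p == p
    if (length(unique(df$label[ix])) < 2 && sum(df$label[ix]) == 0)
      NA_real_ else auc_pr(df$score[ix], df$label[ix])
  })
  expect_equal(ee$mean, mean(refp, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(ee$n_skipped, sum(is.na(refp)))
  # macro mean lies in the convex hull of defined per-unit values
  expect_gte(edd$mean, min(edd$per_unit, na.rm = TRUE))
  expect_lte(edd$mean, max(edd$per_unit, na.rm = TRUE))
})

test_that("the all-positive predictor scores Ee = 0.5 but high Edd", {
  # pairs with at least one true effect; constant scores per pair row
  set.seed(35)
  n_pair <- 30; n_eff <- 8
  lab <- matrix(0, n_pair, n_eff)
  for (p in 1:n_pair) lab[p, sample(n_eff, sample(1:3, 1))] <- 1
  df <- data.frame(i = rep(seq_len(n_pair), n_eff),
                   j = rep(seq_len(n_pair), n_eff) + n_pair,
                   k = rep(seq_len(n_eff), each = n_pair),
                   label = as.vector(lab),
                   score = 1)        # "all effects occur"
  ee <- macro_evaluate(df, "Ee", "auc_roc")
  expect_equal(ee$mean, 0.5)
  expect_equal(ee$n_skipped, 0)
})

test_that("perfect predictions give macro means of 1 for both metrics", {
  set.seed(36)
  df <- data.frame(i = rep(1:10, 4), j = rep(11:20, 4),
                   k = rep(1:4, each = 10))
  df$label <- rbinom(40, 1, 0.4)
  df$score <- df$label
  for (m in c("auc_roc", "auc_pr")) {
    expect_equal(macro_evaluate(df, "Edd", m)$mean, 1)
    expect_equal(macro_evaluate(df, "Ee", m)$mean, 1)
  }
})

test_that("prevalence-rescaled AUC-PR is self-consistent and matches resampling", {
  set.seed(37)
  n <- 2000
  s <- rnorm(n) + 0.8 * (l <- rbinom(n, 1, 0.15))
  emp <- mean(l)
  expect_equal(rescale_pr_to_prevalence(s, l, emp), auc_pr(s, l),
               tolerance = 1e-6)
  expect_equal(rescale_pr_to_prevalence(l + 0, l, 0.3), 1)
  # oracle: subsample negatives to a balanced set and average over resamples
  # (the subsampled average-precision estimator carries a small positive
  # finite-sample bias, hence the Monte-Carlo tolerance)
  target <- 0.5
  n_pos <- sum(l)
  reps <- replicate(200, {
    keep_neg <- sample(which(l == 0), n_pos)
    ix <- c(which(l == 1), keep_neg)
    auc_pr(s[ix], l[ix])
  })
  expect_lt(abs(rescale_pr_to_prevalence(s, l, target) - mean(reps)), 0.015)
})
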