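make_preds <- function(n_drugs, n_effects, labels, scores, scheme = "dde") {
  pr <- which(upper.tri(matrix(0, n_drugs, n_drugs)), arr.ind = TRUE)
  df <- data.frame(i = rep(pr[, 1], n_effects), j = rep(pr[, 2], n_effects),
                   k = rep(seq_len(n_effects), each = nrow(pr)),
                   label = labels, score = scores)
  fake_predictions(df, scheme, n_drugs, n_effects)
}

test_that("zero-label sigma follows the population convention", {
  p <- make_preds(3, 1, labels = c(0, 0, 1), scores = c(-1, 1, 5))
  expect_equal(zero_label_sigma(p), 1)
  p2 <- make_preds(3, 1, labels = c(0, 0, 1), scores = c(0.2, 0.2, 5))
  expect_warning(s <- zero_label_sigma(p2), "identical")
  expect_equal(s, 0)
  set.seed(61)
  sc <- rnorm(60)
  lb <- rbinom(60, 1, 0.3)
  p3 <- make_preds(5, 6, labels = lb, scores = sc)
  z <- sc[lb == 0]
  expect_equal(zero_label_sigma(p3), sqrt(mean((z - mean(z))^2)))
  expect_error(zero_label_sigma(make_preds(3, 1, c(1, 1, 0), c(1, 1, 0))),
               "at least two")
})

test_that("planted high scores are detected exactly and shrink with the multiplier", {
  set.seed(62)
  n_drugs <- 12; n_effects <- 5
  n_cells <- trikrr:::n_pairs(n_drugs) * n_effects
  labels <- rep(0, n_cells)
  scores <- rnorm(n_cells, 0, 0.1)
  planted <- sample(n_cells, 16)
  scores[planted] <- scores[planted] + 10 * 0.1
  p <- make_preds(n_drugs, n_effects, labels, scores)
  rep3 <- detect_effects(p, multiplier = 3)
  expect_setequal(which(scores > rep3$thresholds[1]),
                  planted[scores[planted] > rep3$thresholds[1]])
  # every detected triplet scores above the threshold
  expect_true(all(rep3$detected$score > rep3$thresholds[1]))
  # monotone: growing multiplier never adds detections
  sizes <- sapply(c(1, 2, 3, 5, 50), function(m)
    detect_effects(p, multiplier = m)$n_detected)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(detect_effects(p, multiplier = 1e6)$n_detected, 0)
  expect_error(detect_effects(p, multiplier = -1), "positive")
})

test_that("shifted zero-labels are recovered at the planted rate with pair summaries", {
  set.seed(63)
  n_drugs <- 20; n_effects <- 8
  n_cells <- trikrr:::n_pairs(n_drugs) * n_effects  # 1520
  labels <- rbinom(n_cells, 1, 0.1)
  scores <- rnorm(n_cells, 0, 1)
  zero_ix <- which(labels == 0)
  shifted <- sample(zero_ix, round(0.05 * length(zero_ix)))
  scores[shifted] <- scores[shifted] + 10
  p <- make_preds(n_drugs, n_effects, labels, scores)
  rep3 <- detect_effects(p, multiplier = 3)
  frac <- rep3$n_detected / length(zero_ix)
  expect_lt(abs(frac - 0.05), 0.02)
  # pair-level summaries match an exhaustive recount
  det <- rep3$detected
  det_pairs <- unique(paste(det$i, det$j))
  expect_equal(rep3$distinct_pairs, length(det_pairs))
  df <- p$scores
  lab_pairs <- unique(paste(df$i, df$j)[df$label == 1])
  expect_equal(rep3$pairs_with_known_other_effects,
               sum(det_pairs %in% lab_pairs))
  expect_equal(rep3$new_pairs,
               sum(!det_pairs %in% lab_pairs))
  expect_equal(rep3$fraction_of_all_triplets, rep3$n_detected / n_cells)
})

test_that("the union across models contains each model's detections", {
  set.seed(64)
  n_cells <- trikrr:::n_pairs(10) * 4
  labels <- rbinom(n_cells, 1, 0.1)
  s1 <- rnorm(n_cells); s2 <- s1 + rnorm(n_cells, 0, 0.5)
  p1 <- make_preds(10, 4, labels, s1)
  p2 <- make_preds(10, 4, labels, s2)
  both <- detect_effects(list(edd = p1, ee = p2))
  one <- detect_effects(p1)
  key_both <- with(both$detected, paste(i, j, k))
  key_one <- with(one$detected, paste(i, j, k))
  expect_true(all(key_one %in% key_both))
  expect_true(all(c("edd", "ee") %in% names(both$detected)))
  expect_equal(sum(both$detected$edd), one$n_detected)
})

test_that("new-drug schemes threshold the single score distribution and confirm pairs", {
  set.seed(65)
  n_drugs <- 16; n_effects <- 6
  n_cells <- trikrr:::n_pairs(n_drugs) * n_effects
  labels <- rbinom(n_cells, 1, 0.08)
  # informative scores: positives shifted up
  scores <- rnorm(n_cells, 0, 1) + 6 * labels
  p <- make_preds(n_drugs, n_effects, labels, scores, scheme = "d_de")
  rep3 <- detect_effects(p)
  expect_equal(rep3$population, "all")
  expect_false(is.na(rep3$confirmed_pair_fraction))
  # enrichment: detected pairs are interacting more often than the base rate
  base <- length(unique(with(p$scores[p$scores$label == 1, ],
                             paste(i, j)))) / trikrr:::n_pairs(n_drugs)
  expect_gt(rep3$confirmed_pair_fraction, base)
})
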