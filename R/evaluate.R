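#' Area under the ROC curve
#'
#' Probability that a uniformly random positive outranks a uniformly random
#' negative, with ties counted one half (the rank-sum / trapezoidal-ROC
#' estimator).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), same length.
#' @return AUC-ROC in `[0, 1]`, or `NA` when only one class is present (the
#'   undefined marker consumed by [macro_evaluate()]).
#' @export
auc_roc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision estimator: walking thresholds from the highest score
#' down, precision is computed at each threshold and weighted by the recall
#' gained there (step interpolation; no linear interpolation between
#' operating points). Tied scores enter as a single operating point. The
#' no-skill value of this estimator is the positive prevalence.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in `[0, 1]`, or `NA` when there is no positive.
#' @export
auc_pr <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  p <- sum(labels == 1)
  if (p == 0L) return(NA_real_)
  op <- roc_points(scores, labels)
  sum(diff(c(0, op$tp)) * op$tp / (op$tp + op$fp)) / p
}

check_binary_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have the same length")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("`labels` must be binary (0/1)")
  if (any(!is.finite(scores))) stop("`scores` must be finite")
  labels
}

## Cumulative (TP, FP) at each distinct score threshold, highest first.
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  last <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  list(tp = cumsum(l)[last], fp = cumsum(1 - l)[last])
}

#' Macro-averaged evaluation over effects or drug-drug pairs
#'
#' Arranges pooled test predictions into a matrix with drug-drug pairs as
#' rows and effects as columns and macro-averages a metric over one margin:
#'
#' * `"Edd"` — the metric per *effect* (column), over all test pairs of that
#'   effect, then averaged: how well the model discriminates interacting from
#'   non-interacting pairs for a given effect.
#' * `"Ee"` — the metric per *pair* (row), over all effects, then averaged:
#'   how well the model picks the right effects for a given pair.
#'
#' Units whose test labels are single-class have an undefined metric; they
#' are skipped (not imputed) and counted in `n_skipped` so the choice stays
#' visible. The full per-unit distribution is retained.
#'
#' @param preds a `"cv_predictions"` object from [cv_predict()], or a data
#'   frame with columns `i`, `j`, `k`, `label`, `score`.
#' @param scheme `"Edd"` (per effect) or `"Ee"` (per pair).
#' @param metric `"auc_roc"` or `"auc_pr"`.
#' @return an object of class `"evaluation_result"`: `per_unit` (named
#'   vector of per-unit values, `NA` for skipped units), `mean`,
#'   `n_skipped`, plus the scheme/metric labels.
#' @examples
#' df <- data.frame(i = 1, j = 2:5, k = rep(1:2, each = 4),
#'                  label = rep(c(0, 1), 4), score = runif(8))
#' macro_evaluate(df, "Edd", "auc_roc")
#' @export
macro_evaluate <- function(preds, scheme = c("Edd", "Ee"),
                           metric = c("auc_roc", "auc_pr")) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  df <- if (inherits(preds, "cv_predictions")) preds$scores else
    as.data.frame(preds)
  need <- c("i", "j", "k", "label", "score")
  if (!all(need %in% names(df)))
    stop("`preds` needs columns: ", paste(need, collapse = ", "))
  fun <- if (metric == "auc_roc") auc_roc else auc_pr
  unit <- if (scheme == "Edd") df$k else paste(pmin(df$i, df$j),
                                               pmax(df$i, df$j), sep = "-")
  groups <- split(seq_len(nrow(df)), unit)
  per_unit <- vapply(groups, function(ix) fun(df$score[ix], df$label[ix]),
                     numeric(1L))
  defined <- !is.na(per_unit)
  if (!any(defined))
    stop("no unit with a defined metric (all single-class)")
  structure(list(scheme = scheme, metric = metric, per_unit = per_unit,
                 mean = mean(per_unit[defined]),
                 n_units = length(per_unit), n_skipped = sum(!defined)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("%s macro %s: mean %.4f over %d units (%d skipped)\n",
              x$scheme, toupper(gsub("auc_", "AUC-", x$metric)), x$mean,
              x$n_units - x$n_skipped, x$n_skipped))
  invisible(x)
}

#' Tidy per-unit table of an evaluation
#'
#' @param x an `"evaluation_result"`.
#' @param ... ignored.
#' @export
as.data.frame.evaluation_result <- function(x, ...) {
  data.frame(unit = names(x$per_unit), scheme = x$scheme, metric = x$metric,
             value = unname(x$per_unit), row.names = NULL)
}

#' AUC-PR recalculated at a target class prevalence
#'
#' Recomputes the precision-recall curve as if the class balance were
#' `target_prevalence`: at every ROC operating point the precision is
#' replaced by \deqn{\pi' TPR / (\pi' TPR + (1 - \pi') FPR)} and the curve is
#' integrated with the same average-precision rule as [auc_pr()] (recall
#' increments as weights). With `target_prevalence` equal to the empirical
#' prevalence this reproduces [auc_pr()] exactly. Used to compare results
#' evaluated on the full imbalanced data with results reported on balanced
#' subsamples (no-skill 0.5).
#'
#' @inheritParams auc_roc
#' @param target_prevalence assumed positive fraction, in (0, 1).
#' @return adjusted AUC-PR in `[0, 1]`, `NA` if a class is missing.
#' @export
rescale_pr_to_prevalence <- function(scores, labels, target_prevalence) {
  labels <- check_binary_labels(scores, labels)
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must be in (0, 1)")
  p <- sum(labels == 1)
  n <- sum(labels == 0)
  if (p == 0L || n == 0L) return(NA_real_)
  op <- roc_points(scores, labels)
  tpr <- op$tp / p
  fpr <- op$fp / n
  pi2 <- target_prevalence
  denom <- pi2 * tpr + (1 - pi2) * fpr
  prec <- ifelse(denom > 0, pi2 * tpr / denom, 0)
  sum(diff(c(0, tpr)) * prec)
}
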