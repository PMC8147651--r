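#' Standard deviation of the zero-label score distribution
#'
#' Pooled test predictions for zero-labelled triplets pile up in a
#' distribution centered near zero; its standard deviation (population
#' convention, divisor n) sets the scale of the detection threshold.
#'
#' @param preds a `"cv_predictions"` object or a data frame with columns
#'   `score` and `label`.
#' @return positive scalar; a degenerate (zero-spread) distribution is
#'   returned with a warning since thresholding then degenerates.
#' @export
zero_label_sigma <- function(preds) {
  df <- if (inherits(preds, "cv_predictions")) preds$scores else
    as.data.frame(preds)
  s <- df$score[df$label == 0]
  if (length(s) < 2L)
    stop("need at least two zero-labelled test scores")
  out <- sd_pop(s)
  if (out == 0)
    warning("all zero-label scores identical; 3-sigma thresholding degenerates")
  out
}

#' Detect candidate new interaction effects with a 3-sigma rule
#'
#' For each supplied model's pooled test predictions, triplets scoring above
#' `multiplier` times the standard deviation of the reference score
#' distribution are flagged; flags are united across models (a triplet is
#' detected if any model flags it) with per-model provenance retained.
#'
#' Two reference conventions, matching how the tasks are analysed:
#' * `population = "zero_label"` (tasks with known pairs, held-out triplets /
#'   pairs): sigma is computed on zero-labelled test scores and only
#'   zero-labelled triplets are candidates — detections are *new* effects on
#'   top of the labelled data.
#' * `population = "all"` (new-drug tasks): all test scores form a single
#'   distribution; all test triplets are candidates, and detected pairs are
#'   afterwards confirmed against the held-back labels
#'   (`confirmed_pair_fraction`).
#'
#' @param preds_by_model a `"cv_predictions"` object or a (optionally named)
#'   list of them — e.g. the four models tuned per evaluation scheme and
#'   metric. All must cover the same test triplets.
#' @param multiplier threshold multiplier (default 3).
#' @param population `"zero_label"` or `"all"`; default `"zero_label"` for
#'   cell-level schemes and `"all"` for drug-level schemes.
#' @return an object of class `"detection_report"` with the thresholds per
#'   model, the detected triplet table (`i`, `j`, `k`, `score` = max over
#'   flagging models, one logical column per model), the detected fraction of
#'   all possible canonical triplets, and pair-level summaries: distinct
#'   detected pairs, pairs with at least one known effect in the labels
#'   (count and fraction) versus completely new pairs.
#' @export
detect_effects <- function(preds_by_model, multiplier = 3,
                           population = NULL) {
  if (inherits(preds_by_model, "cv_predictions"))
    preds_by_model <- list(model1 = preds_by_model)
  stopifnot(length(preds_by_model) >= 1L)
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0)
    stop("`multiplier` must be a positive number")
  if (is.null(names(preds_by_model)) || any(names(preds_by_model) == ""))
    names(preds_by_model) <- paste0("model", seq_along(preds_by_model))
  p1 <- preds_by_model[[1L]]
  stopifnot(inherits(p1, "cv_predictions"))
  if (is.null(population))
    population <- if (p1$scheme %in% c("d_de", "d_d_e")) "all" else
      "zero_label"
  population <- match.arg(population, c("zero_label", "all"))
  key0 <- with(p1$scores, paste(i, j, k))
  flags <- matrix(FALSE, nrow(p1$scores), length(preds_by_model),
                  dimnames = list(NULL, names(preds_by_model)))
  thresholds <- numeric(length(preds_by_model))
  names(thresholds) <- names(preds_by_model)
  scoremat <- matrix(NA_real_, nrow(p1$scores), length(preds_by_model))
  for (m in seq_along(preds_by_model)) {
    pm <- preds_by_model[[m]]
    stopifnot(inherits(pm, "cv_predictions"))
    if (!identical(with(pm$scores, paste(i, j, k)), key0))
      stop("prediction sets do not cover the same test triplets")
    sig <- if (population == "zero_label") zero_label_sigma(pm) else
      sd_pop(pm$scores$score)
    thresholds[m] <- multiplier * sig
    cand <- if (population == "zero_label") pm$scores$label == 0 else
      rep(TRUE, nrow(pm$scores))
    flags[, m] <- cand & pm$scores$score > thresholds[m]
    scoremat[, m] <- pm$scores$score
  }
  any_flag <- rowSums(flags) > 0
  det <- p1$scores[any_flag, c("i", "j", "k", "label")]
  det$score <- apply(scoremat[any_flag, , drop = FALSE], 1L, max)
  det <- cbind(det, flags[any_flag, , drop = FALSE])
  rownames(det) <- NULL
  nd <- p1$n_drugs
  total <- n_pairs(nd) * p1$n_effects
  det_pairs <- unique(pair_id(det$i, det$j, nd))
  # pairs that already have >= 1 known (labelled) effect anywhere
  lab_pairs <- unique(pair_id(p1$scores$i[p1$scores$label == 1],
                              p1$scores$j[p1$scores$label == 1], nd))
  known <- sum(det_pairs %in% lab_pairs)
  structure(list(
    multiplier = multiplier, population = population,
    thresholds = thresholds, detected = det,
    n_detected = nrow(det),
    fraction_of_all_triplets = nrow(det) / total,
    distinct_pairs = length(det_pairs),
    pairs_with_known_other_effects = known,
    pairs_with_known_other_effects_fraction =
      if (length(det_pairs)) known / length(det_pairs) else NA_real_,
    new_pairs = length(det_pairs) - known,
    confirmed_pair_fraction = if (population == "all" && length(det_pairs))
      known / length(det_pairs) else NA_real_,
    scheme = p1$scheme),
    class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("3-sigma detection report (scheme %s, multiplier %g, %s scores)\n",
              x$scheme, x$multiplier,
              if (x$population == "zero_label") "zero-label" else "all"))
  cat(sprintf("  thresholds: %s\n",
              paste(sprintf("%s=%.4g", names(x$thresholds), x$thresholds),
                    collapse = ", ")))
  cat(sprintf("  detected triplets: %d (%.3f%% of all possible)\n",
              x$n_detected, 100 * x$fraction_of_all_triplets))
  cat(sprintf("  distinct pairs: %d — %d with known other effects (%.1f%%), %d new\n",
              x$distinct_pairs, x$pairs_with_known_other_effects,
              100 * x$pairs_with_known_other_effects_fraction, x$new_pairs))
  if (!is.na(x$confirmed_pair_fraction))
    cat(sprintf("  confirmed interacting-pair fraction: %.1f%%\n",
                100 * x$confirmed_pair_fraction))
  invisible(x)
}

#' Tabular export of a detection report
#'
#' @param x a `"detection_report"`.
#' @param tensor optional `"triplet_tensor"` used to translate indices back
#'   to drug/effect identifiers.
#' @param ... ignored.
#' @export
as.data.frame.detection_report <- function(x, tensor = NULL, ...) {
  det <- x$detected
  if (!is.null(tensor)) {
    det$drug_a <- tensor$drug_ids[det$i]
    det$drug_b <- tensor$drug_ids[det$j]
    det$effect <- tensor$effect_ids[det$k]
    det <- det[, c("drug_a", "drug_b", "effect",
                   setdiff(names(det), c("i", "j", "k", "drug_a", "drug_b",
                                         "effect")))]
  }
  det
}
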