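#' Default regularization grids per prediction task
#'
#' Log-spaced grids for the regularization triple, one decade apart by
#' default, matching the ranges used for each task in the source protocol:
#' for held-out triplets (`"dde"`) and held-out pairs (`"dd_e"`) the two drug
#' roles are symmetric, \eqn{\lambda_1 = \lambda_2 \in [10^{-6}, 10^{-1}]}
#' and \eqn{\lambda_3 \in [10^{-4}, 10^{1}]}; for two new drugs (`"d_d_e"`)
#' \eqn{\lambda_1 = \lambda_2 \in [10^{-4}, 10^{1}]}, \eqn{\lambda_3 \in
#' [10^{-4}, 10^{1}]}; for one new drug (`"d_de"`) the roles differ and
#' \eqn{\lambda_1 \in [10^{-3}, 10^{-1}]}, \eqn{\lambda_2 \in [10^{-6},
#' 10^{-1}]}, \eqn{\lambda_3 \in [10^{-1}, 10^{1}]} (more regularization on
#' the unseen-drug mode). Range endpoints are always included.
#'
#' @param scheme prediction task, as in [make_folds()].
#' @param points_per_decade grid density (default 1).
#' @return an object of class `"tuning_grid"`: `lambda1`, `lambda2`,
#'   `lambda3` (numeric ranges), `tied` (`TRUE` when \eqn{\lambda_1 =
#'   \lambda_2} is enforced) and `triples` (data frame of all candidate
#'   triples). Ties in tuning are broken toward larger lambda.
#' @export
default_grid <- function(scheme = c("dde", "dd_e", "d_de", "d_d_e"),
                         points_per_decade = 1) {
  scheme <- match.arg(scheme)
  rng <- switch(scheme,
    dde = , dd_e = list(l1 = c(-6, -1), l2 = c(-6, -1), l3 = c(-4, 1),
                        tied = TRUE),
    d_d_e = list(l1 = c(-4, 1), l2 = c(-4, 1), l3 = c(-4, 1), tied = TRUE),
    d_de = list(l1 = c(-3, -1), l2 = c(-6, -1), l3 = c(-1, 1), tied = FALSE))
  gr <- function(lim) 10^seq(lim[1L], lim[2L],
                             by = 1 / points_per_decade)
  l1 <- gr(rng$l1)
  l2 <- gr(rng$l2)
  l3 <- gr(rng$l3)
  triples <- if (rng$tied) {
    expand.grid(lambda1 = l1, lambda3 = l3)[, c(1, 1, 2)]
  } else {
    expand.grid(lambda1 = l1, lambda2 = l2, lambda3 = l3)
  }
  names(triples) <- c("lambda1", "lambda2", "lambda3")
  triples <- triples[order(triples$lambda1, triples$lambda2,
                           triples$lambda3), , drop = FALSE]
  rownames(triples) <- NULL
  structure(list(scheme = scheme, lambda1 = l1, lambda2 = l2, lambda3 = l3,
                 tied = rng$tied, triples = triples,
                 tie_rule = "ties broken toward larger lambda"),
            class = "tuning_grid")
}

#' @export
print.tuning_grid <- function(x, ...) {
  cat(sprintf("Tuning grid for scheme %s (%d triples%s)\n", x$scheme,
              nrow(x$triples), if (x$tied) ", lambda1 = lambda2" else ""))
  cat("  lambda1:", format(range(x$lambda1)), "\n")
  cat("  lambda2:", format(range(x$lambda2)), "\n")
  cat("  lambda3:", format(range(x$lambda3)), "\n")
  invisible(x)
}

#' Tune the regularization triple by inner cross-validation
#'
#' Selects \eqn{(\lambda_1, \lambda_2, \lambda_3)} for a task by running an
#' inner cross-validation of the same scheme on the supplied (training)
#' tensor for every grid triple and scoring the pooled inner predictions
#' with a macro-averaged metric. Kernel eigendecompositions per inner fold
#' are computed once and shared across all grid points, so the grid sweep
#' costs little more than a single cross-validation. Inner validation
#' defaults to leave-one-drug-out for the drug-level schemes and 10 folds
#' for the cell-level schemes. Ties are broken toward larger lambda (more
#' regularization).
#'
#' The caller is responsible for passing *training* data only (in a nested
#' design, the outer fold's training tensor), so outer test information never
#' reaches the selection.
#'
#' @param x a `"triplet_tensor"` (training data).
#' @param scheme prediction task, see [make_folds()].
#' @param eval_scheme `"Edd"` or `"Ee"`, see [macro_evaluate()].
#' @param metric `"auc_roc"` or `"auc_pr"`.
#' @param grid a `"tuning_grid"`, default [default_grid()] for the scheme.
#' @param n_folds inner fold count; default leave-one-drug-out for
#'   drug-level schemes, 10 otherwise.
#' @param seed seed for the inner fold assignment.
#' @inheritParams cv_predict
#' @return an object of class `"threestep_tuning"`: `best` (named numeric
#'   triple), `table` (data frame: lambda1, lambda2, lambda3, value) and the
#'   selection settings.
#' @export
tune_threestep <- function(x, scheme = c("dde", "dd_e", "d_de", "d_d_e"),
                           eval_scheme = c("Edd", "Ee"),
                           metric = c("auc_roc", "auc_pr"),
                           grid = NULL, n_folds = NULL, seed = 1,
                           kd = NULL, features = NULL,
                           effect_method = c("cosine", "tanimoto")) {
  scheme <- match.arg(scheme)
  eval_scheme <- match.arg(eval_scheme)
  metric <- match.arg(metric)
  effect_method <- match.arg(effect_method)
  if (is.null(grid)) grid <- default_grid(scheme)
  stopifnot(inherits(grid, "tuning_grid"))
  if (is.null(n_folds)) {
    n_folds <- if (scheme %in% c("d_de", "d_d_e")) x$n_drugs else 10L
  }
  plan <- make_folds(scheme, x, n_folds = n_folds, seed = seed)
  triples <- lapply(seq_len(nrow(grid$triples)),
                    function(r) as.numeric(grid$triples[r, ]))
  preds <- cv_predict(x, plan, lambda = triples, kd = kd,
                      features = features, effect_method = effect_method)
  vals <- vapply(preds, function(p) {
    ev <- tryCatch(macro_evaluate(p, eval_scheme, metric),
                   error = function(e) NULL)
    if (is.null(ev)) NA_real_ else ev$mean
  }, numeric(1L))
  if (all(is.na(vals)))
    stop("tuning failed: metric undefined at every grid point")
  tab <- cbind(grid$triples, value = vals)
  # grid is sorted ascending in lambda; last argmax = largest tied lambda
  best_row <- max(which(vals == max(vals, na.rm = TRUE)))
  best <- as.numeric(grid$triples[best_row, ])
  names(best) <- c("lambda1", "lambda2", "lambda3")
  structure(list(best = best, table = tab, scheme = scheme,
                 eval_scheme = eval_scheme, metric = metric, seed = seed,
                 n_folds = plan$n_folds),
            class = "threestep_tuning")
}

#' @export
print.threestep_tuning <- function(x, ...) {
  cat(sprintf("Regularization tuning (%s, %s, %s; %d inner folds)\n",
              x$scheme, x$eval_scheme, x$metric, x$n_folds))
  cat(sprintf("  best: lambda = (%g, %g, %g), %s = %.4f\n",
              x$best[1L], x$best[2L], x$best[3L], x$metric,
              max(x$table$value, na.rm = TRUE)))
  invisible(x)
}
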