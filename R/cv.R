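#' Cross-validation fold plans for the four prediction tasks
#'
#' Builds the fold assignment for one of the four task-specific
#' cross-validation schemes. Each scheme holds out a different unit, matching
#' the task it validates:
#'
#' * `"dde"` — held-out triplets: canonical drug-drug-effect cells are
#'   randomly partitioned over folds (both orientations of a cell travel
#'   together). The tensor-completion task. Because every cell is eventually
#'   a test cell, pairs are additionally split into two halves for fold-safe
#'   effect-kernel construction (see [half_fold_pair_split()]); `n_folds`
#'   must be even.
#' * `"dd_e"` — held-out pairs: unordered drug pairs are partitioned, each
#'   carrying all effects. First cold-start task: no effect of a test pair
#'   is ever in training.
#' * `"d_de"` — held-out single drugs: drugs are partitioned; a fold's test
#'   triplets pair a test ("new") drug with a training drug (new drug in the
#'   first slot). Triplets with both drugs in the test fold are discarded.
#'   Training excludes every triplet involving any test drug.
#' * `"d_d_e"` — held-out drug pairs ("two new drugs"): drugs are
#'   partitioned; test triplets have both drugs in the test fold; triplets
#'   mixing test and training drugs are discarded.
#'
#' @param scheme one of `"dde"`, `"dd_e"`, `"d_de"`, `"d_d_e"`.
#' @param x a `"triplet_tensor"`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the random assignment (uniform shuffling, no
#'   stratification).
#' @return an object of class `"cv_plan"`.
#' @examples
#' sim <- simulate_polypharmacy(n_drugs = 12, n_effects = 4, seed = 1)
#' plan <- make_folds("d_de", sim$tensor, n_folds = 3, seed = 7)
#' plan
#' @export
make_folds <- function(scheme = c("dde", "dd_e", "d_de", "d_d_e"), x,
                       n_folds = 10, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(x, "triplet_tensor"))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("`n_folds` must be at least 2")
  nd <- x$n_drugs
  np <- n_pairs(nd)
  plan <- list(scheme = scheme, n_folds = n_folds, seed = as.integer(seed),
               n_drugs = nd, n_effects = x$n_effects)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  if (scheme == "dde") {
    if (n_folds %% 2L != 0L)
      stop("the held-out-triplet scheme needs an even number of folds ",
           "(pair-half effect-kernel construction)")
    if (np < 2L) stop("need at least two drug pairs")
    plan$pair_half <- balanced_groups(np, 2L)
    cf <- matrix(0L, np, x$n_effects)
    g1 <- plan$pair_half == 1L
    # cells of half-1 pairs are tested in folds 1..k/2 (kernel from half 2),
    # cells of half-2 pairs in folds k/2+1..k (kernel from half 1)
    cf[g1, ] <- balanced_groups(sum(g1) * x$n_effects, n_folds %/% 2L)
    cf[!g1, ] <- balanced_groups(sum(!g1) * x$n_effects, n_folds %/% 2L) +
      n_folds %/% 2L
    plan$cell_fold <- cf
  } else if (scheme == "dd_e") {
    if (np < n_folds) stop("more folds than drug pairs")
    plan$pair_fold <- balanced_groups(np, n_folds)
  } else {
    if (nd < n_folds) stop("more folds than drugs")
    plan$drug_fold <- balanced_groups(nd, n_folds)
  }
  structure(plan, class = "cv_plan")
}

## Random balanced assignment of n items to g groups.
balanced_groups <- function(n, g) {
  sample(rep_len(seq_len(g), n))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cv_plan <- function(x, ...) {
  lab <- c(dde = "held-out triplets (tensor completion)",
           dd_e = "held-out drug pairs (cold start 1)",
           d_de = "held-out single drugs (cold start 2)",
           d_d_e = "held-out drug pairs, both new (cold start 3)")
  cat(sprintf("CV plan: scheme %s — %s\n", x$scheme, lab[[x$scheme]]))
  cat(sprintf("  %d folds, seed %d, %d drugs x %d effects\n",
              x$n_folds, x$seed, x$n_drugs, x$n_effects))
  invisible(x)
}

#' Fold roles of one fold
#'
#' Expands a plan into the concrete test / train / discard structure of one
#' fold: the test triplets (canonical, oriented for `"d_de"`), the training
#' drugs, and the pairs whose labels may feed the fold's effect kernel.
#'
#' @param plan a `"cv_plan"`.
#' @param fold fold number in `1:n_folds`.
#' @return a list with elements `test` (matrix of test triplets; columns
#'   `i`, `j`, `k`; for `"d_de"` column `i` is the new drug so `i > j` is
#'   possible), `train_drugs`, `test_drugs` (drug-level schemes),
#'   `zero_cells` (pair/effect cells zeroed in the training tensor, cell
#'   schemes), `kernel_pairs` (pair-index matrix for the effect kernel) and
#'   `discard` (discarded canonical triplets, drug-level schemes).
#' @export
fold_roles <- function(plan, fold) {
  stopifnot(inherits(plan, "cv_plan"), fold >= 1L, fold <= plan$n_folds)
  nd <- plan$n_drugs
  ne <- plan$n_effects
  pr <- all_pairs(nd)
  out <- list(test_drugs = integer(0), train_drugs = seq_len(nd),
              discard = NULL)
  if (plan$scheme == "dde") {
    cells <- which(plan$cell_fold == fold, arr.ind = TRUE)
    out$test <- cbind(i = pr[cells[, 1L], 1L], j = pr[cells[, 1L], 2L],
                      k = cells[, 2L])
    out$zero_cells <- cells
    hs <- half_fold_pair_split(plan)
    out$kernel_pairs <- if (hs$kernel_half[fold] == 1L) hs$half1 else hs$half2
  } else if (plan$scheme == "dd_e") {
    tp <- which(plan$pair_fold == fold)
    out$test <- cbind(i = rep(pr[tp, 1L], ne), j = rep(pr[tp, 2L], ne),
                      k = rep(seq_len(ne), each = length(tp)))
    out$zero_cells <- cbind(rep(tp, ne), rep(seq_len(ne), each = length(tp)))
    out$kernel_pairs <- pr[plan$pair_fold != fold, , drop = FALSE]
  } else {
    te <- which(plan$drug_fold == fold)
    tr <- which(plan$drug_fold != fold)
    out$test_drugs <- te
    out$train_drugs <- tr
    out$kernel_pairs <- pr[pr[, 1L] %in% tr & pr[, 2L] %in% tr, , drop = FALSE]
    if (plan$scheme == "d_de") {
      # new drug in slot i (mode 1); both-test pairs discarded
      out$test <- cbind(i = rep(te, each = length(tr)),
                        j = rep(tr, length(te)),
                        k = rep(seq_len(ne),
                                each = length(te) * length(tr)))
      dim(out$test) <- c(length(te) * length(tr) * ne, 3L)
      colnames(out$test) <- c("i", "j", "k")
      dp <- pr[pr[, 1L] %in% te & pr[, 2L] %in% te, , drop = FALSE]
      out$discard <- cbind(i = rep(dp[, 1L], ne), j = rep(dp[, 2L], ne),
                           k = rep(seq_len(ne), each = nrow(dp)))
    } else {
      tp <- pr[pr[, 1L] %in% te & pr[, 2L] %in% te, , drop = FALSE]
      out$test <- cbind(i = rep(tp[, 1L], ne), j = rep(tp[, 2L], ne),
                        k = rep(seq_len(ne), each = nrow(tp)))
      dp <- pr[xor(pr[, 1L] %in% te, pr[, 2L] %in% te), , drop = FALSE]
      out$discard <- cbind(i = rep(dp[, 1L], ne), j = rep(dp[, 2L], ne),
                           k = rep(seq_len(ne), each = nrow(dp)))
    }
  }
  out
}

#' Serializable audit table of a fold plan
#'
#' One row per assignment unit at the plan's granularity: cells
#' (`i`, `j`, `k`, `fold`) for `"dde"`, pairs (`i`, `j`, `fold`) for
#' `"dd_e"`, drugs (`drug`, `fold`) for the drug-level schemes.
#'
#' @param x a `"cv_plan"`.
#' @param ... ignored.
#' @export
as.data.frame.cv_plan <- function(x, ...) {
  pr <- all_pairs(x$n_drugs)
  if (x$scheme == "dde") {
    cells <- which(x$cell_fold > 0L, arr.ind = TRUE)
    data.frame(i = pr[cells[, 1L], 1L], j = pr[cells[, 1L], 2L],
               k = cells[, 2L], fold = x$cell_fold[cells],
               pair_half = x$pair_half[cells[, 1L]])
  } else if (x$scheme == "dd_e") {
    data.frame(i = pr[, 1L], j = pr[, 2L], fold = x$pair_fold)
  } else {
    data.frame(drug = seq_len(x$n_drugs), fold = x$drug_fold)
  }
}

#' Contamination audit of a fold plan
#'
#' Exhaustively verifies, by direct membership scans independent of the
#' prediction code path, that no fold's training inputs contain information
#' about its own test triplets:
#' no test cell keeps its label in the training tensor; no test pair indexes
#' a feature column of the fold's label-derived effect kernel; for drug-level
#' schemes, no training triplet involves a test drug.
#'
#' @param plan a `"cv_plan"`.
#' @param x the `"triplet_tensor"` the plan was built for.
#' @return `TRUE` invisibly; stops with a contamination error otherwise.
#' @export
audit_folds <- function(plan, x) {
  stopifnot(inherits(plan, "cv_plan"), inherits(x, "triplet_tensor"))
  nd <- plan$n_drugs
  for (f in seq_len(plan$n_folds)) {
    r <- fold_roles(plan, f)
    test_pairs <- unique(pair_id(r$test[, "i"], r$test[, "j"], nd))
    kp <- pair_id(r$kernel_pairs[, 1L], r$kernel_pairs[, 2L], nd)
    if (any(test_pairs %in% kp))
      stop("contamination: fold ", f,
           " effect kernel built from a test pair")
    if (plan$scheme %in% c("d_de", "d_d_e")) {
      # training tensor is the sub-tensor over training drugs
      if (any(r$test_drugs %in% r$train_drugs))
        stop("contamination: fold ", f, " test drug among training drugs")
      bad <- r$kernel_pairs[, 1L] %in% r$test_drugs |
        r$kernel_pairs[, 2L] %in% r$test_drugs
      if (any(bad))
        stop("contamination: fold ", f, " kernel pair involves a test drug")
    } else {
      # training labels: test cells must be zeroed
      ytr <- training_tensor(as.array(x), r)
      if (any(ytr[r$test[, c("i", "j", "k"), drop = FALSE]] != 0) ||
          any(ytr[r$test[, c("j", "i", "k"), drop = FALSE]] != 0))
        stop("contamination: fold ", f, " test label present in training tensor")
    }
  }
  invisible(TRUE)
}

## Zero the held-out cells (both orientations) of a dense label tensor.
training_tensor <- function(y, roles) {
  if (!is.null(roles$zero_cells)) {
    y[roles$test[, c("i", "j", "k"), drop = FALSE]] <- 0
    y[roles$test[, c("j", "i", "k"), drop = FALSE]] <- 0
  }
  y
}

#' Pooled out-of-fold predictions
#'
#' Runs the fold plan: for every fold, a three-step model is refitted from
#' scratch on that fold's training inputs only — held-out cells zeroed (cell
#' schemes) or test drugs dropped from the tensor and both kernels
#' (drug-level schemes), with the effect kernel rebuilt from the fold's
#' training pairs — and its test triplets are scored. Scores are pooled
#' across folds into one score per canonical test triplet; in the
#' single-drug scheme the two orientations of a pair (each tested in the
#' fold of one of its drugs) are averaged.
#'
#' Kernel eigendecompositions are cached and shared wherever the training
#' kernel does not change across folds (the full drug kernel for the cell
#' schemes; each pair-half effect kernel for `"dde"`), and across all entries
#' of `lambda` when a list of regularization triples is supplied — refitting
#' along a grid then costs only the spectral rescaling.
#'
#' @param x a `"triplet_tensor"`.
#' @param plan a `"cv_plan"` from [make_folds()].
#' @param lambda a length-3 regularization triple, or a list of such triples
#'   (a grid) to be evaluated with shared fold contexts.
#' @param kd optional precomputed drug kernel; else built from `features`.
#' @param features binary drug feature matrix (used when `kd` is `NULL`).
#' @param effect_method effect-kernel similarity, see [effect_kernel()].
#' @return a `"cv_predictions"` object (or a list of them when `lambda` is a
#'   list): `scores` is a data frame of pooled canonical test triplets
#'   (`i < j`) with columns `i`, `j`, `k`, `label`, `score`; `unpooled`
#'   retains per-fold, per-orientation rows for provenance.
#' @export
cv_predict <- function(x, plan, lambda, kd = NULL, features = NULL,
                       effect_method = c("cosine", "tanimoto")) {
  single <- !is.list(lambda)
  if (single) lambda <- list(lambda)
  effect_method <- match.arg(effect_method)
  stopifnot(inherits(x, "triplet_tensor"), inherits(plan, "cv_plan"))
  for (l in lambda) check_lambda(l)
  if (is.null(kd)) {
    if (is.null(features))
      stop("supply a drug kernel `kd` or a drug feature matrix `features`")
    kd <- gaussian_kernel(features)
  }
  if (nrow(kd) != x$n_drugs) stop("`kd` size must match the tensor")
  y <- as.array(x)
  eig_d_full <- if (plan$scheme %in% c("dde", "dd_e")) eig_psd(kd) else NULL
  ke_cache <- new.env(parent = emptyenv())
  rows <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    ctx <- fold_context(y, x, kd, eig_d_full, plan, f, effect_method, ke_cache)
    rows[[f]] <- lapply(lambda, function(l) fold_scores(ctx, l))
  }
  out <- lapply(seq_along(lambda), function(li) {
    unpooled <- do.call(rbind, lapply(rows, `[[`, li))
    pool_predictions(unpooled, x, plan, lambda[[li]])
  })
  if (single) out[[1L]] else out
}

## Per-fold training context: training tensor (or sub-tensor), cached
## eigensystems, and the test-query similarity blocks.
fold_context <- function(y, x, kd, eig_d_full, plan, fold, effect_method,
                         ke_cache) {
  r <- fold_roles(plan, fold)
  nd <- plan$n_drugs
  if (plan$scheme %in% c("dde", "dd_e")) {
    key <- if (plan$scheme == "dde")
      paste0("half", half_fold_pair_split(plan)$kernel_half[fold])
    else paste0("fold", fold)
    if (!is.null(ke_cache[[key]])) {
      kee <- ke_cache[[key]]
    } else {
      ke <- effect_kernel(x, train_pairs = r$kernel_pairs,
                          method = effect_method)
      kee <- list(ke = ke, eig = eig_psd(ke))
      ke_cache[[key]] <- kee
    }
    list(scheme = plan$scheme, fold = fold,
         ytrain = training_tensor(y, r), roles = r,
         eig = list(d = eig_d_full, e = kee$eig))
  } else {
    tr <- r$train_drugs
    ke <- effect_kernel(x, train_pairs = r$kernel_pairs,
                        method = effect_method)
    list(scheme = plan$scheme, fold = fold,
         ytrain = y[tr, tr, , drop = FALSE], roles = r,
         eig = list(d = eig_psd(kd[tr, tr, drop = FALSE]), e = eig_psd(ke)),
         kd_cross = kd[r$test_drugs, tr, drop = FALSE],
         kd_train = kd[tr, tr, drop = FALSE])
  }
}

## Score the fold's test triplets for one regularization triple.
fold_scores <- function(ctx, lambda) {
  r <- ctx$roles
  if (ctx$scheme %in% c("dde", "dd_e")) {
    fit <- threestep_core(ctx$ytrain, ctx$eig, lambda, want = "F")
    s <- (fit$F[r$test[, c("i", "j", "k"), drop = FALSE]] +
            fit$F[r$test[, c("j", "i", "k"), drop = FALSE]]) / 2
    data.frame(i = r$test[, "i"], j = r$test[, "j"], k = r$test[, "k"],
               fold = ctx$fold, score = s)
  } else {
    fit <- threestep_core(ctx$ytrain, ctx$eig, lambda, want = "A")
    ke <- ctx$eig$e$vectors %*% (t(ctx$eig$e$vectors) * ctx$eig$e$values)
    te <- r$test_drugs
    tr <- r$train_drugs
    if (ctx$scheme == "d_de") {
      g <- tmode(tmode(tmode(fit$A, ctx$kd_cross, 1L), ctx$kd_train, 2L),
                 ke, 3L)
      idx <- cbind(match(r$test[, "i"], te), match(r$test[, "j"], tr),
                   r$test[, "k"])
      data.frame(i = r$test[, "i"], j = r$test[, "j"], k = r$test[, "k"],
                 fold = ctx$fold, score = g[idx])
    } else {
      if (length(te) < 2L || nrow(r$test) == 0L)
        return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                          fold = integer(0), score = numeric(0)))
      g <- tmode(tmode(tmode(fit$A, ctx$kd_cross, 1L), ctx$kd_cross, 2L),
                 ke, 3L)
      a <- match(r$test[, "i"], te)
      b <- match(r$test[, "j"], te)
      s <- (g[cbind(a, b, r$test[, "k"])] + g[cbind(b, a, r$test[, "k"])]) / 2
      data.frame(i = r$test[, "i"], j = r$test[, "j"], k = r$test[, "k"],
                 fold = ctx$fold, score = s)
    }
  }
}

## Pool per-fold, per-orientation scores into one score per canonical triplet.
pool_predictions <- function(unpooled, x, plan, lambda) {
  ci <- pmin(unpooled$i, unpooled$j)
  cj <- pmax(unpooled$i, unpooled$j)
  key <- (pair_id(ci, cj, x$n_drugs) - 1) * x$n_effects + unpooled$k
  score <- tapply(unpooled$score, key, mean)
  ukey <- as.numeric(names(score))
  pid <- (ukey - 1) %/% x$n_effects + 1
  pr <- all_pairs(x$n_drugs)
  scores <- data.frame(i = pr[pid, 1L], j = pr[pid, 2L],
                       k = as.integer((ukey - 1) %% x$n_effects + 1),
                       score = as.numeric(score))
  ydense <- as.array(x)
  scores$label <- ydense[as.matrix(scores[, c("i", "j", "k")])]
  scores <- scores[, c("i", "j", "k", "label", "score")]
  structure(list(scores = scores, unpooled = unpooled, scheme = plan$scheme,
                 n_folds = plan$n_folds, seed = plan$seed, lambda = lambda,
                 n_drugs = x$n_drugs, n_effects = x$n_effects),
            class = "cv_predictions")
}

#' @export
print.cv_predictions <- function(x, ...) {
  cat(sprintf(
    "Pooled out-of-fold predictions (scheme %s, %d folds, lambda = %g/%g/%g)\n",
    x$scheme, x$n_folds, x$lambda[1L], x$lambda[2L], x$lambda[3L]))
  cat(sprintf("  %d canonical test triplets (%d positive)\n",
              nrow(x$scores), sum(x$scores$label)))
  invisible(x)
}

#' Mode-wise hold-out correction of ridge predictions
#'
#' Given a ridge smoother `h` (see [hat_matrix()]) with in-sample fitted
#' values \eqn{\hat y = H y}, returns the predictions for the index block
#' `s` of a model refitted *without* the labels in `s`:
#' \deqn{\hat y_S^{(-S)} = (I - H_{SS})^{-1} (\hat y_S - H_{SS} y_S).}
#' For a single index this is the classical leave-one-out shortcut
#' \eqn{(\hat y_i - H_{ii} y_i) / (1 - H_{ii})}. The corrected predictions do
#' not depend on the held-out labels (the deflated smoother has a zero block
#' on `s`).
#'
#' @param h smoother matrix.
#' @param y label vector.
#' @param s integer vector of held-out indices.
#' @return numeric vector of corrected predictions, one per element of `s`.
#' @export
block_deflate <- function(h, y, s) {
  stopifnot(is.matrix(h), nrow(h) == ncol(h), length(y) == nrow(h))
  s <- as.integer(s)
  if (any(s < 1L | s > nrow(h))) stop("`s` out of range")
  yhat <- h %*% y
  hss <- h[s, s, drop = FALSE]
  m <- diag(length(s)) - hss
  if (rcond(m) < 1e-12)
    stop("I - H_SS numerically singular; use an explicit refit for this fold")
  drop(solve(m, yhat[s] - hss %*% y[s]))
}
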