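#' Gaussian kernel on binary drug feature vectors
#'
#' Drug similarity from mono-drug (single-drug) effect profiles:
#' \deqn{k_d(d_i, d_j) = \exp(-\|d_i - d_j\|^2 / \gamma)}
#' where \eqn{d_i} is the binary indicator vector of mono-drug effects. The
#' default bandwidth `"auto"` sets \eqn{\gamma} to the feature dimension, the
#' natural scale for binary indicators (the squared distance between two such
#' vectors is at most the dimension).
#'
#' @param features binary matrix, drugs in rows, mono-effect indicators in
#'   columns. Row order must match the drug order of the label tensor.
#' @param bandwidth positive scalar \eqn{\gamma}, or `"auto"` for the number
#'   of feature columns.
#' @return a symmetric `n x n` kernel matrix with unit diagonal and entries
#'   in `(0, 1]`, with attribute `kind = "drug"`.
#' @examples
#' x <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
#' gaussian_kernel(x)[1, 2]  # exp(-2/4)
#' @export
gaussian_kernel <- function(features, bandwidth = "auto") {
  features <- as.matrix(features)
  if (!all(features %in% c(0, 1)))
    stop("`features` must be a binary indicator matrix")
  if (identical(bandwidth, "auto")) bandwidth <- ncol(features)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("`bandwidth` must be a positive scalar or \"auto\"")
  sq <- rowSums(features^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(features)
  d2[d2 < 0] <- 0  # guard tiny negatives from cancellation
  k <- exp(-d2 / bandwidth)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  structure(k, kind = "drug")
}

#' Label-derived effect kernel
#'
#' Effect similarity built from training labels: each effect \eqn{e_k} is
#' represented by the binary incidence vector over a designated set of
#' *training* drug-drug pairs (1 when that pair causes the effect), and
#' similarity is \deqn{k_e(e_k, e_l) = e_k \cdot e_l / (\|e_k\| \|e_l\|)}
#' as printed in the source method (the cosine form of Tanimoto similarity on
#' binary vectors). `method = "tanimoto"` instead uses the classical binary
#' Tanimoto/Jaccard \eqn{a \cdot b / (\|a\|^2 + \|b\|^2 - a \cdot b)}.
#'
#' Restricting incidence to training pairs is what keeps this kernel fold-safe
#' in cross-validation: a test triplet's pair must never contribute a feature
#' column to the kernel used to predict it (see [half_fold_pair_split()] for
#' the held-out-triplet scheme).
#'
#' Effects caused by none of the training pairs have an all-zero incidence
#' vector; their off-diagonal similarities are set to 0 and the diagonal to 1,
#' with a warning.
#'
#' @param x a `"triplet_tensor"` providing the labels.
#' @param train_pairs integer matrix with columns `i`, `j` (unordered pairs,
#'   any orientation) designating the training pairs; default all pairs.
#' @param method `"cosine"` (as printed; default) or `"tanimoto"`.
#' @return a symmetric `n_effects x n_effects` kernel matrix with entries in
#'   `[0, 1]` and unit diagonal, attribute `kind = "effect"`.
#' @export
effect_kernel <- function(x, train_pairs = NULL,
                          method = c("cosine", "tanimoto")) {
  stopifnot(inherits(x, "triplet_tensor"))
  method <- match.arg(method)
  inc <- effect_incidence(x, train_pairs)
  k <- tcrossprod(inc)                    # n_effects x n_effects co-incidence
  nrm2 <- diag(k)
  empty <- nrm2 == 0
  if (any(empty))
    warning(sum(empty), " effect(s) with no incident training pair; ",
            "similarities set to 0 off-diagonal")
  denom <- if (method == "cosine") {
    outer(sqrt(nrm2), sqrt(nrm2))
  } else {
    outer(nrm2, nrm2, "+") - k
  }
  ke <- ifelse(denom > 0, k / denom, 0)
  ke <- (ke + t(ke)) / 2
  diag(ke) <- 1
  structure(ke, kind = "effect")
}

## Binary incidence matrix: effects x training pairs, 1 when the pair causes
## the effect. Only pairs listed in `train_pairs` become columns.
effect_incidence <- function(x, train_pairs = NULL) {
  n <- x$n_drugs
  if (is.null(train_pairs)) train_pairs <- all_pairs(n)
  train_pairs <- as.matrix(train_pairs)
  if (nrow(train_pairs) == 0L) stop("`train_pairs` must be non-empty")
  pid <- pair_id(train_pairs[, 1L], train_pairs[, 2L], n)
  if (anyDuplicated(pid)) stop("duplicated pairs in `train_pairs`")
  inc <- matrix(0, x$n_effects, length(pid))
  tr <- x$triplets
  hit <- match(pair_id(tr[, "i"], tr[, "j"], n), pid)
  keep <- !is.na(hit)
  if (any(keep)) inc[cbind(tr[keep, "k"], hit[keep])] <- 1
  inc
}

#' Pair halves for effect kernels in the held-out-triplet scheme
#'
#' In the held-out-triplet (`"dde"`) cross-validation scheme every cell is
#' eventually a test cell, so no single pair set is training for all folds.
#' The fold plan therefore splits the unordered drug pairs into two halves:
#' the first `n_folds/2` folds draw their test triplets from one half and
#' build the effect kernel from the *other* half only, and vice versa, so a
#' test triplet's pair never indexes a kernel feature column.
#'
#' @param plan a `"cv_plan"` for scheme `"dde"` (see [make_folds()]).
#' @return a list with `half1`, `half2` (integer pair-index matrices, columns
#'   `i`, `j`) and `kernel_half` (for each fold, which half the effect kernel
#'   is built from: 1 or 2).
#' @export
half_fold_pair_split <- function(plan) {
  stopifnot(inherits(plan, "cv_plan"))
  if (plan$scheme != "dde")
    stop("pair-half splitting applies to the held-out-triplet scheme only")
  if (plan$n_folds %% 2L != 0L)
    stop("the held-out-triplet scheme needs an even number of folds")
  pr <- all_pairs(plan$n_drugs)
  list(half1 = pr[plan$pair_half == 1L, , drop = FALSE],
       half2 = pr[plan$pair_half == 2L, , drop = FALSE],
       kernel_half = ifelse(seq_len(plan$n_folds) <= plan$n_folds / 2L, 2L, 1L))
}
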