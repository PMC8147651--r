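#' Three-step kernel ridge regression for triplet link prediction
#'
#' Fits the three-step kernel ridge regression model for a symmetric binary
#' drug-drug-effect label tensor \eqn{Y}. The prediction function is
#' \deqn{f(d, d', e) = \sum_{a,b,c} A_{abc}\, k_d(d, d_a)\, k_d(d', d_b)\,
#'   k_e(e, e_c)}
#' and the parameter tensor \eqn{A} is defined by requiring that the labels
#' equal the predictions of a regularized variant in which the self-similarity
#' of each training object is inflated by \eqn{\lambda_1}, \eqn{\lambda_2} or
#' \eqn{\lambda_3} (one shift per tensor mode):
#' \deqn{Y = A \times_1 (K_d + \lambda_1 I) \times_2 (K_d + \lambda_2 I)
#'   \times_3 (K_e + \lambda_3 I).}
#' The solution is three tensor contractions of \eqn{Y} with the inverse
#' shifted Gram matrices, computed through eigendecompositions of the two
#' kernels (shifted eigenvalues are inverted; no explicit matrix inverse is
#' formed). The eigendecompositions are cached on the returned object so that
#' refitting along a \eqn{\lambda} grid costs only the cheap spectral part.
#'
#' The three regularization parameters control shrinkage per mode and are how
#' the model adapts to the different cold-start tasks: e.g. predicting for a
#' new drug in the first position calls for a larger \eqn{\lambda_1}.
#'
#' @param y a `"triplet_tensor"` (see [triplet_tensor()]) or a dense symmetric
#'   binary array.
#' @param kd drug kernel matrix (`n_drugs x n_drugs`); if `NULL` and
#'   `features` is given, a [gaussian_kernel()] on `features` is used.
#' @param ke effect kernel matrix (`n_effects x n_effects`); if `NULL`, a
#'   label-derived [effect_kernel()] over all pairs is used (only appropriate
#'   outside cross-validation).
#' @param lambda numeric length-3 vector \eqn{(\lambda_1, \lambda_2,
#'   \lambda_3)}. Strictly positive, except that 0 is allowed when the
#'   corresponding kernel is non-singular.
#' @param features optional binary drug feature matrix used when `kd` is
#'   `NULL`.
#' @return an object of class `"threestep"` with components `A` (parameter
#'   tensor), `fitted.values`, `y`, `kd`, `ke`, `lambda`, `eig` (cached
#'   eigensystems) and `residual` (relative Frobenius residual of the
#'   defining equation; should be at numerical zero).
#' @examples
#' sim <- simulate_polypharmacy(n_drugs = 12, n_effects = 4, seed = 1)
#' fit <- threestep(sim$tensor, features = sim$features,
#'                  lambda = c(0.1, 0.1, 0.1))
#' fit
#' range(fitted(fit) - as.array(sim$tensor))  # shrinkage residuals
#' @seealso [predict.threestep()], [hat_matrix()], [cv_predict()],
#'   [tune_threestep()]
#' @export
threestep <- function(y, kd = NULL, ke = NULL, lambda = c(1, 1, 1),
                      features = NULL) {
  cl <- match.call()
  if (inherits(y, "triplet_tensor")) {
    ids <- list(drugs = y$drug_ids, effects = y$effect_ids)
    yt <- y
    y <- as.array(y)
  } else {
    y <- as_validated_label_array(y)
    ids <- list(drugs = dimnames(y)[[1]], effects = dimnames(y)[[3]])
    yt <- NULL
  }
  d <- dim(y)
  if (is.null(kd)) {
    if (is.null(features))
      stop("supply a drug kernel `kd` or a drug feature matrix `features`")
    kd <- gaussian_kernel(features)
  }
  if (is.null(ke)) {
    if (is.null(yt)) yt <- as_triplet_tensor(y)
    ke <- effect_kernel(yt)
  }
  check_lambda(lambda)
  if (nrow(kd) != d[1L]) stop("`kd` size must equal the number of drugs")
  if (nrow(ke) != d[3L]) stop("`ke` size must equal the number of effects")
  eig <- list(d = eig_psd(kd), e = eig_psd(ke))
  fit <- threestep_core(y, eig, lambda)
  res <- eq2_residual(fit$A, kd, ke, lambda, y)
  structure(
    list(A = fit$A, fitted.values = fit$F, y = y, kd = kd, ke = ke,
         lambda = lambda, eig = eig, residual = res, ids = ids, call = cl),
    class = "threestep")
}

## Eigendecomposition of a symmetric PSD kernel; small negative eigenvalues
## from floating point are clipped to zero.
eig_psd <- function(k, clip = 1e-10) {
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  e$values[e$values < 0 & e$values > -clip] <- 0
  e
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 3L || any(!is.finite(lambda)) ||
      any(lambda < 0))
    stop("`lambda` must be three finite non-negative reals")
}

## Spectral solve shared by the fitter and the cross-validation refits.
## Returns the parameter tensor A and in-sample fitted values F.
threestep_core <- function(y, eig, lambda, want = c("A", "F")) {
  s1 <- eig$d$values + lambda[1L]
  s2 <- eig$d$values + lambda[2L]
  s3 <- eig$e$values + lambda[3L]
  for (m in 1:3) {
    s <- list(s1, s2, s3)[[m]]
    if (any(s <= 0))
      stop("singular shifted Gram matrix in mode ", m,
           " (eigenvalue + lambda <= 0); increase lambda", m)
  }
  ud <- eig$d$vectors
  ue <- eig$e$vectors
  core <- tmode(tmode(tmode(y, t(ud), 1L), t(ud), 2L), t(ue), 3L)
  inv_shift <- 1 / outer3(s1, s2, s3)
  out <- list()
  if ("A" %in% want) {
    a <- core * inv_shift
    out$A <- tmode(tmode(tmode(a, ud, 1L), ud, 2L), ue, 3L)
  }
  if ("F" %in% want) {
    f <- core * inv_shift *
      outer3(eig$d$values, eig$d$values, eig$e$values)
    out$F <- tmode(tmode(tmode(f, ud, 1L), ud, 2L), ue, 3L)
  }
  out
}

outer3 <- function(a, b, c) {
  outer(outer(a, b), c)
}

## Relative Frobenius residual of the defining equation: contract A with the
## three shifted Gram matrices and compare with Y.
eq2_residual <- function(a, kd, ke, lambda, y) {
  lhs <- tmode(tmode(tmode(a, kd + diag(lambda[1L], nrow(kd)), 1L),
                     kd + diag(lambda[2L], nrow(kd)), 2L),
               ke + diag(lambda[3L], nrow(ke)), 3L)
  ny <- sqrt(sum(y^2))
  if (ny == 0) return(sqrt(sum(lhs^2)))
  sqrt(sum((lhs - y)^2)) / ny
}

as_validated_label_array <- function(y) {
  y <- as.array(y)
  d <- dim(y)
  if (length(d) != 3L || d[1L] != d[2L])
    stop("`y` must be an n_drugs x n_drugs x n_effects array")
  y
}

#' Ridge smoother (hat) matrix of a kernel
#'
#' The per-mode smoother \eqn{H = K (K + \lambda I)^{-1}} implied by the
#' shifted Gram factors of the model's defining equation, computed through the
#' eigendecomposition of `K`. Its eigenvalues lie in `[0, 1)` for
#' `lambda > 0`; its diagonal drives leave-out shortcuts (see
#' [block_deflate()]).
#'
#' @param k symmetric PSD kernel matrix.
#' @param lambda non-negative ridge parameter (0 only for non-singular `k`).
#' @return the `n x n` smoother matrix.
#' @export
hat_matrix <- function(k, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a non-negative scalar")
  e <- eig_psd(k)
  s <- e$values + lambda
  if (any(s <= 0)) stop("singular shifted Gram matrix; increase lambda")
  e$vectors %*% (t(e$vectors) * (e$values / s))
}

#' Predict from a three-step model
#'
#' Evaluates the prediction function at new triplets given their kernel
#' similarities to the training drugs and effects: the triple contraction of
#' the parameter tensor with a drug-similarity vector for each drug slot and
#' an effect-similarity vector.
#'
#' @param object a fitted `"threestep"` model.
#' @param drug1,drug2 similarity vectors (length `n_drugs`) or matrices
#'   (`n_new x n_drugs`) of the query drugs against the training drugs;
#'   default the training drug kernel (in-sample).
#' @param effect similarity vector/matrix against the training effects;
#'   default the training effect kernel.
#' @param ... ignored.
#' @return an array of scores `n1 x n2 x n3`; dropped to a scalar when all
#'   three inputs are vectors. Larger scores mean the effect is more likely
#'   for the pair.
#' @export
predict.threestep <- function(object, drug1 = NULL, drug2 = NULL,
                              effect = NULL, ...) {
  nd <- nrow(object$kd)
  ne <- nrow(object$ke)
  vecs <- !is.null(drug1) && is.null(dim(drug1)) &&
    !is.null(drug2) && is.null(dim(drug2)) &&
    !is.null(effect) && is.null(dim(effect))
  q1 <- query_matrix(drug1 %||% object$kd, nd, "drug1")
  q2 <- query_matrix(drug2 %||% object$kd, nd, "drug2")
  q3 <- query_matrix(effect %||% object$ke, ne, "effect")
  out <- tmode(tmode(tmode(object$A, q1, 1L), q2, 2L), q3, 3L)
  if (vecs) drop(out) else out
}

query_matrix <- function(x, n, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != n)
    stop("`", what, "` similarity vectors must have length ", n)
  x
}

#' @export
fitted.threestep <- function(object, ...) object$fitted.values

#' @export
residuals.threestep <- function(object, ...) object$y - object$fitted.values

#' @export
coef.threestep <- function(object, ...) object$A

#' @export
print.threestep <- function(x, ...) {
  d <- dim(x$y)
  cat("Three-step kernel ridge regression\n")
  cat(sprintf("  tensor: %d drugs x %d effects (%d positive cells)\n",
              d[1L], d[3L], sum(x$y) / 2))
  cat(sprintf("  lambda: (%g, %g, %g)\n",
              x$lambda[1L], x$lambda[2L], x$lambda[3L]))
  cat(sprintf("  defining-equation residual (rel. Frobenius): %.2e\n",
              x$residual))
  invisible(x)
}

#' @export
summary.threestep <- function(object, ...) {
  f <- object$fitted.values
  y <- object$y
  n <- dim(y)[1L]
  off <- which(upper.tri(matrix(0, n, n)))  # canonical cells, every effect
  idx <- as.vector(outer(off, (seq_len(dim(y)[3L]) - 1L) * n * n, "+"))
  out <- list(
    call = object$call, dim = dim(y), lambda = object$lambda,
    residual = object$residual,
    eig_range = list(drug = range(object$eig$d$values),
                     effect = range(object$eig$e$values)),
    fitted_by_label = tapply(f[idx], y[idx], summary))
  class(out) <- "summary.threestep"
  out
}

#' @export
print.summary.threestep <- function(x, ...) {
  cat("Three-step kernel ridge regression\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\nTensor: %d x %d x %d, lambda = (%g, %g, %g)\n",
              x$dim[1L], x$dim[2L], x$dim[3L],
              x$lambda[1L], x$lambda[2L], x$lambda[3L]))
  cat(sprintf("Defining-equation residual: %.2e\n", x$residual))
  cat(sprintf("Kernel eigenvalue ranges: drug [%.3g, %.3g], effect [%.3g, %.3g]\n",
              x$eig_range$drug[1L], x$eig_range$drug[2L],
              x$eig_range$effect[1L], x$eig_range$effect[2L]))
  cat("\nIn-sample fitted values by label (canonical cells):\n")
  print(x$fitted_by_label)
  invisible(x)
}

#' Plot method: in-sample score distributions by label
#'
#' Overlaid histograms of fitted scores for zero- and one-labelled canonical
#' cells; a well-regularized fit separates the two while keeping the
#' zero-label mass near zero (the distribution the 3-sigma detection rule
#' thresholds).
#'
#' @param x a `"threestep"` fit.
#' @param breaks passed to [graphics::hist()].
#' @param ... further arguments passed to plot.
#' @export
plot.threestep <- function(x, breaks = 40, ...) {
  f <- x$fitted.values
  y <- x$y
  n <- dim(y)[1L]
  off <- which(upper.tri(matrix(0, n, n)))
  idx <- as.vector(outer(off, (seq_len(dim(y)[3L]) - 1L) * n * n, "+"))
  s <- f[idx]
  l <- y[idx]
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  h0 <- graphics::hist(s[l == 0], breaks = h$breaks, plot = FALSE)
  h1 <- graphics::hist(s[l == 1], breaks = h$breaks, plot = FALSE)
  graphics::plot(h0, col = grDevices::grey(0.8), border = NA, freq = FALSE,
                 main = "Fitted scores by label", xlab = "score", ...)
  graphics::plot(h1, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, freq = FALSE, add = TRUE)
  graphics::legend("topright", fill = c(grDevices::grey(0.8), "firebrick"),
                   legend = c("label 0", "label 1"), bty = "n")
  invisible(x)
}

#' Save / load a three-step model archive
#'
#' Serializes a fitted model as a single archive file of keyed arrays (the
#' two kernels, the regularization triple, the parameter tensor and the label
#' tensor in triplet form). [read_threestep()] reconstructs the full fitted
#' object, recomputing the cached eigensystems and fitted values.
#'
#' @param object a `"threestep"` fit.
#' @param path file path for the archive.
#' @return `write_threestep` returns `path` invisibly; `read_threestep`
#'   returns a `"threestep"` object.
#' @export
write_threestep <- function(object, path) {
  stopifnot(inherits(object, "threestep"))
  saveRDS(list(format = "trikrr-threestep-1",
               kd = unclass(object$kd), ke = unclass(object$ke),
               lambda = object$lambda, A = object$A, y = object$y,
               ids = object$ids),
          path)
  invisible(path)
}

#' @rdname write_threestep
#' @export
read_threestep <- function(path) {
  ar <- readRDS(path)
  if (!identical(ar$format, "trikrr-threestep-1"))
    stop("not a three-step model archive: ", path)
  fit <- threestep(ar$y, kd = ar$kd, ke = ar$ke, lambda = ar$lambda)
  fit$ids <- ar$ids
  if (max(abs(fit$A - ar$A)) > 1e-8)
    warning("re-solved parameter tensor differs from the archived one")
  fit
}
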