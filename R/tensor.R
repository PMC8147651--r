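#' Binary drug-drug-effect label tensor
#'
#' Builds the symmetric binary label tensor \eqn{Y} at the core of triplet
#' link prediction: \eqn{Y_{ijk} = 1} when the interaction between drugs
#' \eqn{i} and \eqn{j} causes effect \eqn{k}. The tensor is symmetric in its
#' two drug modes (\eqn{Y_{ijk} = Y_{jik}}, drug order carries no meaning) and
#' has a zero drug-diagonal (\eqn{Y_{iik} = 0}, a drug cannot interact with
#' itself). Storage is a canonical triplet list (unordered pairs \eqn{i < j});
#' the dense symmetric array is materialised on demand with
#' [as.array.triplet_tensor()].
#'
#' @param records a data frame of positive triplets with columns `drug_a`,
#'   `drug_b`, `effect` (identifiers, treated as opaque strings) and
#'   optionally `effect_name`. Both orientations of a pair collapse to one
#'   canonical triplet; duplicates are deduplicated. May have zero rows if
#'   vocabularies are supplied.
#' @param drug_ids,effect_ids optional fixed vocabularies (character). When
#'   supplied, records referring to unknown identifiers are an error; when
#'   absent, vocabularies are the sorted identifiers seen in `records`.
#' @param effect_names optional character vector of free-text effect names,
#'   parallel to `effect_ids`.
#' @return an object of class `"triplet_tensor"` with fields `n_drugs`,
#'   `n_effects`, `drug_ids`, `effect_ids`, `effect_names` and `triplets`
#'   (integer matrix with columns `i`, `j`, `k`; `i < j`).
#' @examples
#' rec <- data.frame(drug_a = c("A", "B"), drug_b = c("B", "C"),
#'                   effect = c("e1", "e2"))
#' y <- triplet_tensor(rec)
#' as.array(y)[, , "e1"]
#' positive_prevalence(y)
#' @seealso [positive_prevalence()], [interacting_pair_fraction()],
#'   [as_triplet_tensor()]
#' @export
triplet_tensor <- function(records, drug_ids = NULL, effect_ids = NULL,
                           effect_names = NULL) {
  if (!is.data.frame(records))
    stop("`records` must be a data frame of (drug_a, drug_b, effect) rows")
  need <- c("drug_a", "drug_b", "effect")
  if (!all(need %in% names(records)))
    stop("`records` needs columns: ", paste(need, collapse = ", "))
  da <- as.character(records$drug_a)
  db <- as.character(records$drug_b)
  ef <- as.character(records$effect)
  if (any(da == db))
    stop("self-pair record (drug_a == drug_b) violates the zero drug-diagonal")
  if (is.null(drug_ids)) drug_ids <- sort(unique(c(da, db)))
  if (is.null(effect_ids)) effect_ids <- sort(unique(ef))
  drug_ids <- as.character(drug_ids)
  effect_ids <- as.character(effect_ids)
  if (anyDuplicated(drug_ids) || anyDuplicated(effect_ids))
    stop("duplicated identifiers in vocabulary")
  i <- match(da, drug_ids)
  j <- match(db, drug_ids)
  k <- match(ef, effect_ids)
  if (anyNA(i) || anyNA(j))
    stop("unknown drug identifier(s): ",
         paste(unique(c(da, db)[is.na(c(i, j))]), collapse = ", "))
  if (anyNA(k))
    stop("unknown effect identifier(s): ",
         paste(unique(ef[is.na(k)]), collapse = ", "))
  trip <- cbind(i = pmin(i, j), j = pmax(i, j), k = k)
  trip <- unique(trip)
  trip <- trip[order(trip[, "k"], trip[, "j"], trip[, "i"]), , drop = FALSE]
  if (is.null(effect_names) && "effect_name" %in% names(records) &&
      nrow(records) > 0L) {
    effect_names <- records$effect_name[match(effect_ids, ef)]
  }
  structure(
    list(n_drugs = length(drug_ids), n_effects = length(effect_ids),
         drug_ids = drug_ids, effect_ids = effect_ids,
         effect_names = effect_names,
         triplets = matrix(as.integer(trip), ncol = 3L,
                           dimnames = list(NULL, c("i", "j", "k")))),
    class = "triplet_tensor")
}

#' Coerce a dense array to a triplet tensor
#'
#' Validates that `x` is a binary three-way array, symmetric in the two drug
#' modes with a zero drug-diagonal, and converts it to the canonical triplet
#' list representation.
#'
#' @param x a `n_drugs x n_drugs x n_effects` array with entries in `{0, 1}`.
#' @param drug_ids,effect_ids identifier vocabularies; default `d1..dn`,
#'   `e1..em`.
#' @return a `"triplet_tensor"`.
#' @export
as_triplet_tensor <- function(x, drug_ids = NULL, effect_ids = NULL) {
  d <- dim(x)
  if (length(d) != 3L || d[1L] != d[2L])
    stop("`x` must be an n x n x m array")
  if (!all(x %in% c(0, 1))) stop("entries must be binary (0/1)")
  if (max(abs(x - aperm(x, c(2L, 1L, 3L)))) > 0)
    stop("tensor must be symmetric in its two drug modes (Y[i,j,k] == Y[j,i,k])")
  for (k in seq_len(d[3L])) if (any(diag(x[, , k]) != 0))
    stop("drug-diagonal must be zero (Y[i,i,k] == 0)")
  drug_ids <- drug_ids %||% paste0("d", seq_len(d[1L]))
  effect_ids <- effect_ids %||% paste0("e", seq_len(d[3L]))
  idx <- which(x == 1, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  rec <- data.frame(drug_a = drug_ids[idx[, 1L]], drug_b = drug_ids[idx[, 2L]],
                    effect = effect_ids[idx[, 3L]])
  triplet_tensor(rec, drug_ids = drug_ids, effect_ids = effect_ids)
}

#' @export
dim.triplet_tensor <- function(x) c(x$n_drugs, x$n_drugs, x$n_effects)

#' Densify a triplet tensor
#'
#' Materialises the full symmetric `n_drugs x n_drugs x n_effects` 0/1 array
#' (both orientations of each canonical triplet set). The full Decagon tensor
#' is ~400M cells, so densification is explicit and on demand.
#'
#' @param x a `"triplet_tensor"`.
#' @param ... ignored.
#' @return a numeric array with `dimnames` from the identifier vocabularies.
#' @export
as.array.triplet_tensor <- function(x, ...) {
  a <- array(0, dim = dim(x),
             dimnames = list(x$drug_ids, x$drug_ids, x$effect_ids))
  if (nrow(x$triplets) > 0L) {
    t1 <- x$triplets
    a[t1] <- 1
    a[t1[, c(2L, 1L, 3L), drop = FALSE]] <- 1
  }
  a
}

#' Export a triplet tensor to records
#'
#' Inverse of [triplet_tensor()]: one row per canonical positive triplet.
#' Round trip (`triplet_tensor(as.data.frame(x), ...)`) is the identity.
#'
#' @param x a `"triplet_tensor"`.
#' @param ... ignored.
#' @export
as.data.frame.triplet_tensor <- function(x, ...) {
  tr <- x$triplets
  data.frame(drug_a = x$drug_ids[tr[, "i"]],
             drug_b = x$drug_ids[tr[, "j"]],
             effect = x$effect_ids[tr[, "k"]],
             effect_name = if (!is.null(x$effect_names))
               x$effect_names[tr[, "k"]] else x$effect_ids[tr[, "k"]],
             stringsAsFactors = FALSE)
}

#' @export
print.triplet_tensor <- function(x, ...) {
  cat(sprintf("Drug-drug-effect label tensor: %d drugs x %d effects\n",
              x$n_drugs, x$n_effects))
  cat(sprintf("  positive canonical triplets: %d (prevalence %.4f)\n",
              nrow(x$triplets), positive_prevalence(x)))
  cat(sprintf("  interacting pair fraction:   %.4f\n",
              interacting_pair_fraction(x)))
  invisible(x)
}

#' Positive triplet prevalence
#'
#' Fraction of possible canonical (unordered, off-diagonal) drug-drug-effect
#' triplets that carry a positive label. The reference pharmacovigilance
#' benchmark sits at about 2%.
#'
#' @param x a `"triplet_tensor"`.
#' @return a fraction in `[0, 1]`.
#' @export
positive_prevalence <- function(x) {
  stopifnot(inherits(x, "triplet_tensor"))
  tot <- n_pairs(x$n_drugs) * x$n_effects
  if (tot == 0L) return(0)
  nrow(x$triplets) / tot
}

#' Fraction of interacting drug-drug pairs
#'
#' Fraction of unordered drug pairs that cause at least one effect. The
#' reference benchmark sits at about 70%.
#'
#' @param x a `"triplet_tensor"`.
#' @return a fraction in `[0, 1]`.
#' @export
interacting_pair_fraction <- function(x) {
  stopifnot(inherits(x, "triplet_tensor"))
  np <- n_pairs(x$n_drugs)
  if (np == 0L) return(0)
  tr <- x$triplets
  length(unique(pair_id(tr[, "i"], tr[, "j"], x$n_drugs))) / np
}
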