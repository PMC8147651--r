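#' @keywords internal
"_PACKAGE"

## Canonical unordered drug pairs are (i, j) with i < j, enumerated in
## column-major (colex) order: (1,2), (1,3), (2,3), (1,4), ...  This matches
## which(upper.tri(.), arr.ind = TRUE) so pair ids are stable across modules.

all_pairs <- function(n) {
  m <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(m) <- c("i", "j")
  m
}

pair_id <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo == hi)) stop("pair_id: self-pair (i == j) has no canonical id")
  ((hi - 1L) * (hi - 2L)) %/% 2L + lo
}

n_pairs <- function(n) (n * (n - 1L)) %/% 2L

## Mode-n product: contract tensor a (3-way array) with matrix m along `mode`,
## i.e. result[.., r, ..] = sum_s m[r, s] a[.., s, ..].
tmode <- function(a, m, mode) {
  d <- dim(a)
  stopifnot(length(d) == 3L, ncol(m) == d[mode])
  perm <- switch(mode, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  x <- aperm(a, perm)
  dx <- dim(x)
  x <- m %*% matrix(x, nrow = dx[1L])
  x <- array(x, c(nrow(m), dx[2L], dx[3L]))
  aperm(x, order(perm))
}

## Population standard deviation (divisor n, not n - 1).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
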