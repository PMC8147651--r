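#' Read a drug-drug-effect combination CSV
#'
#' Reads the combination-file dialect used by the Decagon polypharmacy
#' distribution: comma-separated, UTF-8, header
#' `STITCH 1, STITCH 2, Polypharmacy Side Effect, Side Effect Name`.
#' Identifiers are opaque strings (compound CID numerals are never parsed as
#' integers — leading zeros are significant). Duplicate (pair, effect) rows
#' and opposite orientations collapse to one record; self-pair rows are
#' skipped with a warning (a drug cannot interact with itself).
#'
#' @param path CSV file path.
#' @return a data frame of triplet records with columns `drug_a`, `drug_b`,
#'   `effect`, `effect_name`, ready for [triplet_tensor()].
#' @export
read_combo_csv <- function(path) {
  df <- read_dialect(path, c("STITCH 1", "STITCH 2",
                             "Polypharmacy Side Effect", "Side Effect Name"))
  names(df) <- c("drug_a", "drug_b", "effect", "effect_name")
  self <- df$drug_a == df$drug_b
  if (any(self)) {
    warning(sum(self), " self-pair row(s) skipped (zero drug-diagonal)")
    df <- df[!self, , drop = FALSE]
  }
  lo <- pmin(df$drug_a, df$drug_b)
  hi <- pmax(df$drug_a, df$drug_b)
  keep <- !duplicated(paste(lo, hi, df$effect, sep = "\r"))
  df <- df[keep, , drop = FALSE]
  df$drug_a <- lo[keep]
  df$drug_b <- hi[keep]
  rownames(df) <- NULL
  df
}

#' Read a mono-drug effect CSV into a binary drug feature matrix
#'
#' Reads the single-drug effect dialect (header
#' `STITCH, Individual Side Effect, Side Effect Name`) and pivots it into a
#' binary drug x mono-effect indicator matrix over the union of mono-effect
#' identifiers (sorted). When a fixed drug vocabulary is supplied, rows are
#' aligned to it and drugs absent from the file get all-zero feature rows
#' with a warning.
#'
#' @param path CSV file path.
#' @param drug_ids optional character vector fixing the row order (e.g. the
#'   `drug_ids` of the label tensor).
#' @return binary matrix with drug identifiers as row names and mono-effect
#'   identifiers as column names.
#' @export
read_mono_csv <- function(path, drug_ids = NULL) {
  df <- read_dialect(path, c("STITCH", "Individual Side Effect",
                             "Side Effect Name"))
  names(df) <- c("drug", "effect", "effect_name")
  if (is.null(drug_ids)) drug_ids <- sort(unique(df$drug))
  effects <- sort(unique(df$effect))
  x <- matrix(0, length(drug_ids), length(effects),
              dimnames = list(drug_ids, effects))
  ri <- match(df$drug, drug_ids)
  known <- !is.na(ri)
  x[cbind(ri[known], match(df$effect[known], effects))] <- 1
  missing <- setdiff(drug_ids, df$drug)
  if (length(missing))
    warning(length(missing),
            " drug(s) absent from the mono file; all-zero feature rows: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
  x
}

read_dialect <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!all(cols %in% names(df)))
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  df <- df[, cols, drop = FALSE]
  bad <- which(apply(df == "" | is.na(df), 1L, any))
  if (length(bad))
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "),
         " (empty field)")
  df
}

#' Write tensors and features in the combination / mono CSV dialects
#'
#' Inverses of [read_combo_csv()] and [read_mono_csv()]; writing a tensor
#' and reading the file back yields an identical tensor (round trip).
#'
#' @param x a `"triplet_tensor"` (`write_combo_csv`) or a binary drug
#'   feature matrix with dimnames (`write_mono_csv`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_combo_csv <- function(x, path) {
  stopifnot(inherits(x, "triplet_tensor"))
  rec <- as.data.frame(x)
  out <- data.frame(`STITCH 1` = rec$drug_a, `STITCH 2` = rec$drug_b,
                    `Polypharmacy Side Effect` = rec$effect,
                    `Side Effect Name` = rec$effect_name,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_combo_csv
#' @export
write_mono_csv <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature matrix needs drug row names and mono-effect column names")
  hit <- which(x == 1, arr.ind = TRUE)
  out <- data.frame(STITCH = rownames(x)[hit[, 1L]],
                    `Individual Side Effect` = colnames(x)[hit[, 2L]],
                    `Side Effect Name` = colnames(x)[hit[, 2L]],
                    check.names = FALSE)
  out <- out[order(out$STITCH, out$`Individual Side Effect`), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep only effects occurring in enough drug combinations
#'
#' Removes effects reported for fewer than `min_pairs` distinct unordered
#' drug pairs, together with their records — the frequency filter applied to
#' the raw mined triplets before modelling (500 combinations in the
#' reference benchmark).
#'
#' @param records triplet record data frame (`drug_a`, `drug_b`, `effect`,
#'   ...).
#' @param min_pairs minimum number of distinct pairs (default 500).
#' @return the filtered record data frame.
#' @export
filter_effects_min_pairs <- function(records, min_pairs = 500) {
  stopifnot(is.data.frame(records),
            all(c("drug_a", "drug_b", "effect") %in% names(records)))
  if (min_pairs <= 1) return(records)
  key <- paste(pmin(records$drug_a, records$drug_b),
               pmax(records$drug_a, records$drug_b), sep = "\r")
  counts <- tapply(key, records$effect, function(k) length(unique(k)))
  keep_effects <- names(counts)[counts >= min_pairs]
  out <- records[records$effect %in% keep_effects, , drop = FALSE]
  rownames(out) <- NULL
  out
}
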