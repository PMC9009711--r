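#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonicalize unordered identifier pairs
#'
#' Sorts each pair so that `a <= b` lexicographically. Used everywhere an
#' unordered gene or OG pair is stored, so that duplicated and swapped pairs
#' collapse to one key.
#'
#' @param a,b character vectors of equal length.
#' @return data.frame with columns `a`, `b` (sorted within each row).
#' @keywords internal
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Stable lexicographic order of a pair table
#' @keywords internal
order_pairs <- function(pairs) {
  pairs[order(pairs$a, pairs$b), , drop = FALSE]
}

abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

#' All unordered pairs of a sorted identifier vector
#'
#' Deterministic (lexicographic) enumeration; errors when the pair count would
#' be unreasonably large for in-memory enumeration.
#' @keywords internal
all_unordered_pairs <- function(ids, max_pairs = 5e6) {
  ids <- sort(unique(as.character(ids)))
  n <- length(ids)
  if (n < 2) return(data.frame(a = character(), b = character()))
  abort_if(choose(n, 2) > max_pairs,
           "%d ids give %.0f pairs; refusing to enumerate more than %.0f",
           n, choose(n, 2), max_pairs)
  idx <- utils::combn(n, 2)
  data.frame(a = ids[idx[1, ]], b = ids[idx[2, ]], stringsAsFactors = FALSE)
}
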