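# Scoring OG pairs by profile similarity and ROC/AUC evaluation.

#' Score OG pairs by cosine profile similarity
#'
#' Each pair is scored as `1 - cosine_distance` between the two OG profiles
#' restricted to the active species subset. Pairs with a member whose profile
#' is all-absent under the subset are dropped (distance undefined) and counted.
#'
#' @param m profile matrix.
#' @param pairs data.frame with columns `a`, `b` (OG ids, rows of `m`).
#' @param species_subset optional character vector of species columns.
#' @return data.frame `a`, `b`, `score`; attribute `dropped_pairs` gives the
#'   number of pairs removed because a member profile was all-absent.
#' @export
score_pairs <- function(m, pairs, species_subset = NULL) {
  abort_if(nrow(pairs) == 0, "no pairs to score")
  missing_og <- setdiff(unique(c(pairs$a, pairs$b)), rownames(m))
  abort_if(length(missing_og) > 0, "pair member(s) not in matrix: %s",
           paste(utils::head(missing_og, 5), collapse = ", "))
  sub <- suppressMessages(subset_profile_matrix(m, species_subset))
  ok <- pairs$a %in% rownames(sub) & pairs$b %in% rownames(sub)
  dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  abort_if(nrow(pairs) == 0, "all pairs dropped: every member all-absent under subset")
  A <- sub[pairs$a, , drop = FALSE]
  B <- sub[pairs$b, , drop = FALSE]
  dot <- rowSums(A * B)
  score <- dot / sqrt(rowSums(A) * rowSums(B))
  out <- data.frame(a = pairs$a, b = pairs$b, score = pmin(pmax(score, 0), 1),
                    stringsAsFactors = FALSE)
  attr(out, "dropped_pairs") <- dropped
  out
}

#' Rank-based AUC with tie half-credit
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted half (Mann-Whitney convention):
#' `(#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos n_neg)`.
#'
#' @param pos_scores,neg_scores numeric score vectors (higher = more likely
#'   interacting).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  abort_if(np == 0 || nn == 0, "need at least one positive and one negative score")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Tie-aware ROC curve
#'
#' Sweeps thresholds over the distinct scores in descending order; a tie group
#' advances the curve diagonally. The trapezoidal area under this curve equals
#' [rank_auc()] exactly.
#'
#' @inheritParams rank_auc
#' @return object of class `roc_result`: list with `points` (data.frame of
#'   `threshold`, `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `auc`,
#'   `n_pos`, `n_neg`, `dropped_pairs`.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  abort_if(np == 0 || nn == 0, "need at least one positive and one negative score")
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tp <- cumsum(tabulate(match(pos_scores, thr), nbins = length(thr)))
  fp <- cumsum(tabulate(match(neg_scores, thr), nbins = length(thr)))
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / nn),
                    tpr = c(0, tp / np))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = np, n_neg = nn,
                 dropped_pairs = 0L),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f  (%d positives, %d negatives, %d pair(s) dropped)\n",
              x$auc, x$n_pos, x$n_neg, x$dropped_pairs))
  invisible(x)
}

#' Evaluate a benchmark under species and OG subsets
#'
#' Restricts the profile matrix to the requested OG rows and species columns,
#' filters the benchmark to pairs whose members survive, scores all pairs by
#' cosine similarity, and returns the tie-aware ROC with provenance.
#'
#' @param m profile matrix.
#' @param bench an `interaction_benchmark` (see [assemble_benchmark()]) or a
#'   list with data.frames `positives` and `negatives` (columns `a`, `b`).
#' @param species_subset,og_subset optional identifier vectors.
#' @return `roc_result` with extra fields `provenance` (subset sizes) and
#'   `dropped_pairs` (pairs lost to all-absent profiles or missing OGs).
#' @export
evaluate_configuration <- function(m, bench, species_subset = NULL, og_subset = NULL) {
  validate_profile_matrix(m)
  if (!is.null(og_subset)) {
    og_subset <- intersect(rownames(m), og_subset)
    abort_if(length(og_subset) == 0, "og_subset shares no OGs with the matrix")
    m <- m[og_subset, , drop = FALSE]
  }
  keep_pairs <- function(p) p[p$a %in% rownames(m) & p$b %in% rownames(m), , drop = FALSE]
  pos <- keep_pairs(bench$positives)
  neg <- keep_pairs(bench$negatives)
  abort_if(nrow(pos) == 0, "benchmark emptied out at OG-subset stage: no positives left")
  abort_if(nrow(neg) == 0, "benchmark emptied out at OG-subset stage: no negatives left")
  filtered_out <- (nrow(bench$positives) - nrow(pos)) + (nrow(bench$negatives) - nrow(neg))

  pos_sc <- score_pairs(m, pos, species_subset)
  neg_sc <- score_pairs(m, neg, species_subset)
  roc <- roc_curve(pos_sc$score, neg_sc$score)
  roc$dropped_pairs <- attr(pos_sc, "dropped_pairs") + attr(neg_sc, "dropped_pairs") +
    filtered_out
  roc$provenance <- list(
    n_species = if (is.null(species_subset)) ncol(m) else length(species_subset),
    n_ogs = nrow(m),
    species_subset = species_subset,
    og_subset = og_subset
  )
  roc
}
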