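# Parsing BioGRID-style interaction tables, evidence filtering, and
# positive/negative benchmark construction.
#
# Records are held as a data.frame with one row per unique unordered gene
# pair: columns gene_a, gene_b (canonically sorted), a list-column pubmed_ids
# (union of publication ids) and n_pubs = lengths(pubmed_ids).

biogrid_default_columns <- function() {
  list(gene_a = "Official Symbol Interactor A",
       gene_b = "Official Symbol Interactor B",
       pubmed = "Pubmed ID",
       system_type = "Experimental System Type",
       organism_a = "Organism Interactor A",
       organism_b = "Organism Interactor B")
}

#' Parse a BioGRID-style physical-interaction table
#'
#' Reads a tab-delimited table (or takes a pre-read data.frame), keeps rows
#' whose experimental-system type is physical and whose both interactors
#' belong to the reference organism, canonicalizes gene pairs (sorted order,
#' self-interactions dropped), and collapses duplicate pairs by taking the
#' union of their PubMed ids.
#'
#' @param x path to a tab-delimited file, or a data.frame.
#' @param organism reference organism identifier; rows where either
#'   interactor's organism differs are excluded. `NULL` disables the check.
#' @param columns named list mapping the roles `gene_a`, `gene_b`, `pubmed`,
#'   `system_type`, `organism_a`, `organism_b` to column names; defaults
#'   follow BioGRID TAB 2.0 headers.
#' @param physical_values values of the system-type column accepted as
#'   physical evidence.
#' @return records data.frame (`gene_a`, `gene_b`, `pubmed_ids` list-column,
#'   `n_pubs`), sorted lexicographically; attributes `n_self_dropped`,
#'   `n_nonphysical`, `n_wrong_organism`, `n_unparsable` hold filter counts.
#' @export
parse_interaction_table <- function(x, organism = NULL,
                                    columns = biogrid_default_columns(),
                                    physical_values = "physical") {
  tab <- if (is.data.frame(x)) {
    x
  } else {
    utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = "", quote = "")
  }
  needed <- c("gene_a", "gene_b", "pubmed", "system_type")
  if (!is.null(organism)) needed <- c(needed, "organism_a", "organism_b")
  for (role in needed) {
    cn <- columns[[role]]
    abort_if(is.null(cn) || !cn %in% names(tab),
             "required column missing: %s (role '%s')", cn %||% "<unset>", role)
  }

  ga <- as.character(tab[[columns$gene_a]])
  gb <- as.character(tab[[columns$gene_b]])
  pm <- as.character(tab[[columns$pubmed]])
  sys <- as.character(tab[[columns$system_type]])

  unparsable <- is.na(ga) | is.na(gb) | !nzchar(ga) | !nzchar(gb) |
    is.na(pm) | !nzchar(pm)
  nonphysical <- !unparsable & !(sys %in% physical_values)
  wrong_org <- rep(FALSE, nrow(tab))
  if (!is.null(organism)) {
    oa <- as.character(tab[[columns$organism_a]])
    ob <- as.character(tab[[columns$organism_b]])
    wrong_org <- !unparsable & !(oa == as.character(organism) &
                                   ob == as.character(organism))
  }
  keep <- !unparsable & !nonphysical & !wrong_org
  ga <- ga[keep]; gb <- gb[keep]; pm <- pm[keep]

  pairs <- canonical_pairs(ga, gb)
  self <- pairs$a == pairs$b
  n_self <- sum(self)
  pairs <- pairs[!self, , drop = FALSE]
  pm <- pm[!self]

  if (sum(unparsable) > 0) {
    message(sprintf("skipped %d unparsable interaction row(s)", sum(unparsable)))
  }

  key <- pair_key(pairs$a, pairs$b)
  pubmed_ids <- lapply(split(pm, key), function(p) sort(unique(p)))
  first <- !duplicated(key)
  rec <- data.frame(gene_a = pairs$a[first], gene_b = pairs$b[first],
                    stringsAsFactors = FALSE)
  rec$pubmed_ids <- pubmed_ids[pair_key(rec$gene_a, rec$gene_b)]
  rec <- rec[order(rec$gene_a, rec$gene_b), , drop = FALSE]
  rownames(rec) <- NULL
  rec$n_pubs <- lengths(rec$pubmed_ids)
  attr(rec, "n_self_dropped") <- n_self
  attr(rec, "n_nonphysical") <- sum(nonphysical)
  attr(rec, "n_wrong_organism") <- sum(wrong_org)
  attr(rec, "n_unparsable") <- sum(unparsable)
  rec
}

#' Retain records supported by enough independent studies
#'
#' @param records records data.frame from [parse_interaction_table()].
#' @param min_pubs minimum number of distinct PubMed ids (default 5,
#'   the "found in at least five independent studies" cut).
#' @return filtered records data.frame.
#' @export
filter_by_evidence <- function(records, min_pubs = 5) {
  abort_if(min_pubs < 1, "min_pubs must be >= 1")
  out <- records[records$n_pubs >= min_pubs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Negative interaction set: well-studied genes never reported together
#'
#' Eligible genes are those participating in at least one record with
#' `min_pubs` or more distinct publications (thoroughly studied, receptive to
#' the assays). Negatives are all unordered pairs of eligible genes that
#' appear in no record at all, at any evidence level: a pair reported even
#' once is never a negative.
#'
#' @param records full (unfiltered) records data.frame.
#' @param min_pubs evidence threshold defining gene eligibility (default 5).
#' @param max_pairs optional cap; when the complement is larger, a seeded
#'   uniform down-sample of that size is returned.
#' @param seed seed for the optional down-sampling.
#' @return data.frame `a`, `b` in deterministic lexicographic order (the
#'   down-sample preserves that order).
#' @export
build_negative_set <- function(records, min_pubs = 5, max_pairs = NULL, seed = 1L) {
  strong <- filter_by_evidence(records, min_pubs)
  eligible <- sort(unique(c(strong$gene_a, strong$gene_b)))
  if (length(eligible) < 2) {
    warning("fewer than 2 eligible genes; empty negative set", call. = FALSE)
    return(data.frame(a = character(), b = character()))
  }
  cand <- all_unordered_pairs(eligible)
  reported <- pair_key(records$gene_a, records$gene_b)
  neg <- cand[!pair_key(cand$a, cand$b) %in% reported, , drop = FALSE]
  neg <- order_pairs(neg)
  rownames(neg) <- NULL
  if (!is.null(max_pairs) && nrow(neg) > max_pairs) {
    idx <- withr::with_seed(seed, sort(sample.int(nrow(neg), max_pairs)))
    neg <- neg[idx, , drop = FALSE]
    rownames(neg) <- NULL
  }
  neg
}

#' Map gene pairs to OG pairs
#'
#' A pair is kept only when both genes map to an OG; pairs whose genes fall in
#' the same OG collapse to a self-pair and are excluded; duplicates (several
#' gene pairs hitting the same OG pair) are deduplicated.
#'
#' @param gene_pairs data.frame with the two gene columns first (or named
#'   `a`/`b` or `gene_a`/`gene_b`).
#' @param gene_to_og named character vector: gene -> OG id.
#' @return data.frame `a`, `b` of unique OG pairs (lexicographic); attributes
#'   `n_unmapped` and `n_self_collapsed` hold drop counts.
#' @export
map_to_og_pairs <- function(gene_pairs, gene_to_og) {
  ga <- gene_pairs[[if ("a" %in% names(gene_pairs)) "a" else
    if ("gene_a" %in% names(gene_pairs)) "gene_a" else 1]]
  gb <- gene_pairs[[if ("b" %in% names(gene_pairs)) "b" else
    if ("gene_b" %in% names(gene_pairs)) "gene_b" else 2]]
  oa <- unname(gene_to_og[as.character(ga)])
  ob <- unname(gene_to_og[as.character(gb)])
  unmapped <- is.na(oa) | is.na(ob)
  self <- !unmapped & oa == ob
  keep <- !unmapped & !self
  pairs <- canonical_pairs(oa[keep], ob[keep])
  pairs <- order_pairs(pairs[!duplicated(pair_key(pairs$a, pairs$b)), , drop = FALSE])
  rownames(pairs) <- NULL
  attr(pairs, "n_unmapped") <- sum(unmapped)
  attr(pairs, "n_self_collapsed") <- sum(self)
  pairs
}

#' Assemble an interaction benchmark of positive and negative OG pairs
#'
#' Maps positive and negative gene pairs to OG pairs, drops pairs whose OGs
#' are not rows of the profile matrix, enforces disjointness (a pair landing
#' in both sets stays a positive), and optionally down-samples the negatives.
#'
#' @param positive_gene_pairs,negative_gene_pairs data.frames of gene pairs.
#' @param gene_to_og named character vector: gene -> OG.
#' @param m profile matrix the benchmark will be evaluated against.
#' @param max_negatives optional seeded down-sampling target for the negative
#'   OG pairs (default: keep all).
#' @param seed seed for the down-sampling.
#' @param provenance optional named list recorded verbatim (filter settings).
#' @return object of class `interaction_benchmark`: list with `positives`,
#'   `negatives` (data.frames `a`, `b`), `provenance`, and `counts` of every
#'   drop decision.
#' @export
assemble_benchmark <- function(positive_gene_pairs, negative_gene_pairs,
                               gene_to_og, m, max_negatives = NULL, seed = 1L,
                               provenance = list()) {
  validate_profile_matrix(m)
  pos <- map_to_og_pairs(positive_gene_pairs, gene_to_og)
  neg <- map_to_og_pairs(negative_gene_pairs, gene_to_og)
  counts <- list(pos_unmapped = attr(pos, "n_unmapped"),
                 pos_self_collapsed = attr(pos, "n_self_collapsed"),
                 neg_unmapped = attr(neg, "n_unmapped"),
                 neg_self_collapsed = attr(neg, "n_self_collapsed"))

  in_matrix <- function(p) p$a %in% rownames(m) & p$b %in% rownames(m)
  counts$pos_not_in_matrix <- sum(!in_matrix(pos))
  counts$neg_not_in_matrix <- sum(!in_matrix(neg))
  pos <- pos[in_matrix(pos), , drop = FALSE]
  neg <- neg[in_matrix(neg), , drop = FALSE]

  overlap <- pair_key(neg$a, neg$b) %in% pair_key(pos$a, pos$b)
  counts$neg_overlapping_pos <- sum(overlap)
  neg <- neg[!overlap, , drop = FALSE]

  abort_if(nrow(pos) == 0, "no positive OG pairs left after mapping/filtering")
  abort_if(nrow(neg) == 0, "no negative OG pairs left after mapping/filtering")

  if (!is.null(max_negatives) && nrow(neg) > max_negatives) {
    idx <- withr::with_seed(seed, sort(sample.int(nrow(neg), max_negatives)))
    counts$neg_downsampled_from <- nrow(neg)
    neg <- neg[idx, , drop = FALSE]
  }
  pos <- data.frame(a = pos$a, b = pos$b, stringsAsFactors = FALSE)
  neg <- data.frame(a = neg$a, b = neg$b, stringsAsFactors = FALSE)
  structure(list(positives = pos, negatives = neg,
                 provenance = provenance, counts = counts),
            class = "interaction_benchmark")
}

#' @export
print.interaction_benchmark <- function(x, ...) {
  cat(sprintf("interaction benchmark: %d positive, %d negative OG pairs\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}
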