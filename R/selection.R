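# Genome- and OG-subset selection: quality extremes, greedy
# diversity/similarity, random nulls, leave-one-out influence, random LECA
# OG subsets.

selection_result <- function(member_ids, criterion, parameters = list()) {
  abort_if(anyDuplicated(member_ids) > 0, "selection members must be unique")
  structure(list(member_ids = as.character(member_ids),
                 criterion = criterion, parameters = parameters),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection [%s]: %d members\n", x$criterion, length(x$member_ids)))
  invisible(x)
}

#' Select genomes by a per-species quality count
#'
#' The `k` species with the smallest (`direction = "least"`) or largest
#' (`"most"`) counts -- e.g. BUSCO absences, so "least" picks high-quality
#' genomes. Ties are broken lexicographically; excluded species (typically
#' the reference interactome species) are never chosen.
#'
#' @param counts named numeric vector: species -> count.
#' @param k number of species to select.
#' @param direction `"least"` or `"most"`.
#' @param exclude character vector of species to leave out.
#' @return `selection_result` with criterion `quality_best`/`quality_worst`.
#' @export
select_by_quality <- function(counts, k, direction = c("least", "most"),
                              exclude = character()) {
  direction <- match.arg(direction)
  pool <- counts[setdiff(names(counts), exclude)]
  abort_if(k > length(pool), "k = %d exceeds the %d selectable species", k,
           length(pool))
  ord <- order(if (direction == "least") pool else -pool, names(pool))
  selection_result(names(pool)[ord][seq_len(k)],
                   criterion = if (direction == "least") "quality_best" else "quality_worst",
                   parameters = list(k = k, direction = direction,
                                     exclude = exclude))
}

#' Greedy selection of maximally diverse or similar genomes
#'
#' All unordered species pairs are sorted by cosine distance (descending for
#' `mode = "diverse"`, ascending for `"similar"`); the set is seeded with the
#' extreme pair, then pairs are visited in order and each member (lexicographic
#' order within a pair) is admitted only if its distance to every species
#' already in the set satisfies the threshold (`>=` for diverse, `<=` for
#' similar), stopping at `k` members.
#'
#' @param d symmetric species distance matrix (see
#'   [species_distance_matrix()]).
#' @param k target set size (>= 2).
#' @param mode `"diverse"` or `"similar"`.
#' @param threshold admission threshold; defaults 0.38 (diverse) and 0.58
#'   (similar).
#' @param auto_relax when the threshold cannot reach `k` members, relax it in
#'   steps of 0.01 (down for diverse, up for similar) and retry instead of
#'   erroring.
#' @return `selection_result`; `parameters$threshold_used` records the final
#'   (possibly relaxed) threshold.
#' @export
select_by_diversity <- function(d, k, mode = c("diverse", "similar"),
                                threshold = NULL, auto_relax = FALSE) {
  mode <- match.arg(mode)
  abort_if(k < 2, "k must be at least 2")
  abort_if(!isTRUE(all.equal(d, t(d))), "distance matrix must be symmetric")
  species <- colnames(d)
  abort_if(k > length(species), "k = %d exceeds the %d species", k, length(species))
  if (is.null(threshold)) threshold <- if (mode == "diverse") 0.38 else 0.58
  abort_if(threshold < 0 || threshold > 1, "threshold must be in [0, 1]")

  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(a = species[idx[, 1]], b = species[idx[, 2]],
                      dist = d[idx], stringsAsFactors = FALSE)
  pairs <- canonical_pairs(pairs$a, pairs$b) |>
    cbind(dist = pairs$dist)
  ord <- if (mode == "diverse") {
    order(-pairs$dist, pairs$a, pairs$b)
  } else {
    order(pairs$dist, pairs$a, pairs$b)
  }
  pairs <- pairs[ord, , drop = FALSE]

  admissible <- function(cand, members, thr) {
    if (cand %in% members) return(FALSE)
    dd <- d[cand, members]
    if (mode == "diverse") all(dd >= thr) else all(dd <= thr)
  }
  run_greedy <- function(thr) {
    members <- c(pairs$a[1], pairs$b[1])
    for (i in seq_len(nrow(pairs))) {
      if (length(members) >= k) break
      for (cand in c(pairs$a[i], pairs$b[i])) {
        if (length(members) >= k) break
        if (admissible(cand, members, thr)) members <- c(members, cand)
      }
    }
    members
  }

  thr <- threshold
  repeat {
    members <- run_greedy(thr)
    if (length(members) >= k) break
    if (!auto_relax) {
      stop(sprintf(paste0("greedy %s selection reached only %d of %d members at ",
                          "threshold %.2f; relax the threshold or set auto_relax"),
                   mode, length(members), k, thr), call. = FALSE)
    }
    thr <- if (mode == "diverse") thr - 0.01 else thr + 0.01
    abort_if(thr < 0 || thr > 1,
             "auto-relax exhausted the threshold range without reaching k = %d", k)
  }
  selection_result(members[seq_len(k)],
                   criterion = mode,
                   parameters = list(k = k, threshold = threshold,
                                     threshold_used = thr, mode = mode))
}

#' Random genome subsets (null distribution backdrop)
#'
#' @param species character vector of species ids.
#' @param k subset size (default 50).
#' @param n_sets number of subsets (default 1000).
#' @param seed RNG seed; the whole list is reproducible from it.
#' @return list of `selection_result`s with criterion `"random"`.
#' @export
random_species_sets <- function(species, k = 50, n_sets = 1000, seed = 1L) {
  abort_if(k > length(species), "k = %d exceeds the %d species", k, length(species))
  abort_if(n_sets < 1, "n_sets must be >= 1")
  withr::with_seed(seed, lapply(seq_len(n_sets), function(i) {
    selection_result(sample(species, k),
                     criterion = "random",
                     parameters = list(k = k, n_sets = n_sets, seed = seed,
                                       index = i))
  }))
}

#' Leave-one-out genome influence on prediction AUC
#'
#' Removes each species in turn from the active set and records
#' `delta_auc = AUC(without species) - AUC(full set)`. A positive delta marks
#' a disadvantageous genome (its removal helps), a negative delta an
#' advantageous one.
#'
#' @param m profile matrix.
#' @param bench interaction benchmark.
#' @param species_subset optional initial species set (default: all columns).
#' @return data.frame `species`, `delta_auc`, plus attribute `auc_full`.
#' @export
leave_one_out_influence <- function(m, bench, species_subset = NULL) {
  species <- species_subset %||% colnames(m)
  base <- evaluate_configuration(m, bench, species_subset = species)$auc
  delta <- vapply(species, function(s) {
    evaluate_configuration(m, bench,
                           species_subset = setdiff(species, s))$auc - base
  }, numeric(1))
  out <- data.frame(species = species, delta_auc = unname(delta),
                    stringsAsFactors = FALSE)
  attr(out, "auc_full") <- base
  out
}

#' Top advantageous and disadvantageous genomes
#'
#' Advantageous genomes are the `k` with the most negative leave-one-out
#' delta (removing them hurts performance); disadvantageous the `k` with the
#' most positive delta. Ties are broken lexicographically.
#'
#' @param influence data.frame from [leave_one_out_influence()].
#' @param k set size.
#' @return list with `advantageous` and `disadvantageous` `selection_result`s.
#' @export
top_influencers <- function(influence, k) {
  if (k > nrow(influence) / 2) {
    warning(sprintf("k = %d exceeds half of the %d species; sets will overlap",
                    k, nrow(influence)), call. = FALSE)
  }
  if (all(influence$delta_auc == 0)) {
    warning("all leave-one-out deltas are zero; ranking is lexicographic only",
            call. = FALSE)
  }
  adv <- influence$species[order(influence$delta_auc, influence$species)][seq_len(k)]
  dis <- influence$species[order(-influence$delta_auc, influence$species)][seq_len(k)]
  list(advantageous = selection_result(adv, "advantageous", list(k = k)),
       disadvantageous = selection_result(dis, "disadvantageous", list(k = k)))
}

#' Random OG subsets (null backdrop for OG selection)
#'
#' Subsets of `round(fraction * N)` OGs drawn uniformly without replacement,
#' reproducible from the seed. Defaults mirror the 63% random LECA OG
#' subsets used as the OG-selection null.
#'
#' @param leca_ogs character vector of OG ids to sample from.
#' @param fraction subset fraction in (0, 1] (default 0.63).
#' @param n_sets number of subsets (default 1000).
#' @param seed RNG seed.
#' @return list of `selection_result`s with criterion `"og_random"`.
#' @export
random_og_subsets <- function(leca_ogs, fraction = 0.63, n_sets = 1000, seed = 1L) {
  abort_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  size <- round(fraction * length(leca_ogs))
  withr::with_seed(seed, lapply(seq_len(n_sets), function(i) {
    selection_result(sample(leca_ogs, size),
                     criterion = "og_random",
                     parameters = list(fraction = fraction, n_sets = n_sets,
                                       seed = seed, index = i))
  }))
}

#' Write / read a selection as round-trippable JSON
#'
#' @param sel `selection_result`.
#' @param path output path.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(list(criterion = sel$criterion,
                            parameters = sel$parameters,
                            member_ids = sel$member_ids),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection_json
#' @param path path to a selection JSON file.
#' @export
read_selection_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection_result(x$member_ids, x$criterion, as.list(x$parameters))
}
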