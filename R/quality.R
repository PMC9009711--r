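# Per-genome quality metrics: BUSCO absence ingestion and the Illogical
# Absences (IA) metric.
#
# An illogical absence is a species where exactly one member of a strongly
# interacting OG pair is present: interaction partners are expected to
# co-occur, so lone absences are suspect (annotation/assembly errors).

#' Load per-species BUSCO absence counts
#'
#' @param x path to a two-column TSV (`species_id`, `absences`) with a header,
#'   or an equivalent data.frame.
#' @param species_universe optional character vector; when given, the table
#'   must cover every species in it.
#' @return named integer vector: species -> absence count.
#' @export
load_busco_absences <- function(x, species_universe = NULL) {
  tab <- if (is.data.frame(x)) x else
    utils::read.delim(x, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 2, "BUSCO table needs columns species_id, absences")
  sp <- as.character(tab[[1]])
  cnt <- tab[[2]]
  dup <- sp[duplicated(sp)]
  abort_if(length(dup) > 0, "species listed twice in BUSCO table: %s",
           paste(unique(dup), collapse = ", "))
  abort_if(any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)),
           "BUSCO absence counts must be non-negative integers")
  counts <- stats::setNames(as.integer(cnt), sp)
  if (!is.null(species_universe)) {
    missing_sp <- setdiff(species_universe, sp)
    abort_if(length(missing_sp) > 0, "BUSCO table is missing species: %s",
             paste(utils::head(missing_sp, 5), collapse = ", "))
    counts <- counts[species_universe]
  }
  counts
}

#' Select the strongest interacting OG pairs
#'
#' Positive benchmark pairs whose profiles are closest in cosine distance on
#' the full matrix. `mode = "fraction"` keeps the `floor(value * N)`
#' lowest-distance pairs (ties broken by lexicographic OG-pair order);
#' `mode = "threshold"` keeps pairs with distance `<= value`.
#'
#' @param m profile matrix.
#' @param positives data.frame of positive OG pairs (`a`, `b`).
#' @param mode `"fraction"` or `"threshold"`.
#' @param value fraction in (0, 1] or distance threshold in `[0, 1]`.
#' @return data.frame `a`, `b`, `distance`, sorted by ascending distance.
#' @export
select_strong_pairs <- function(m, positives, mode = c("fraction", "threshold"),
                                value = 0.1) {
  mode <- match.arg(mode)
  abort_if(nrow(positives) == 0, "no positive pairs supplied")
  scored <- score_pairs(m, positives)
  scored$distance <- 1 - scored$score
  scored <- scored[order(scored$distance, scored$a, scored$b), , drop = FALSE]
  out <- if (mode == "fraction") {
    abort_if(value <= 0 || value > 1, "fraction must be in (0, 1]")
    utils::head(scored, floor(value * nrow(scored)))
  } else {
    scored[scored$distance <= value, , drop = FALSE]
  }
  abort_if(nrow(out) == 0,
           "no pair passed the strong-pair cut; loosen mode/value (%s = %g)",
           mode, value)
  rownames(out) <- NULL
  out[, c("a", "b", "distance")]
}

#' Per-species illogical-absence statistics
#'
#' For every species and every strong pair: both members present increments
#' co-presence, both absent co-absence, and exactly one present an illogical
#' absence. The IA ratio is `ia / (co_absence + ia)` (illogical absences over
#' total interaction absences), `NA` when a species has no absences at all.
#'
#' @param m profile matrix.
#' @param strong_pairs data.frame of OG pairs (`a`, `b`), all rows of `m`.
#' @return data.frame with one row per species: `species`, `co_presence`,
#'   `co_absence`, `ia_count`, `ia_ratio`.
#' @export
illogical_absence_stats <- function(m, strong_pairs) {
  validate_profile_matrix(m)
  missing_og <- setdiff(unique(c(strong_pairs$a, strong_pairs$b)), rownames(m))
  abort_if(length(missing_og) > 0, "pair member(s) not in matrix: %s",
           paste(utils::head(missing_og, 5), collapse = ", "))
  A <- m[strong_pairs$a, , drop = FALSE]
  B <- m[strong_pairs$b, , drop = FALSE]
  co_presence <- colSums(A == 1L & B == 1L)
  co_absence <- colSums(A == 0L & B == 0L)
  ia <- colSums(A != B)
  denom <- co_absence + ia
  ratio <- ifelse(denom > 0, ia / denom, NA_real_)
  data.frame(species = colnames(m),
             co_presence = as.integer(co_presence),
             co_absence = as.integer(co_absence),
             ia_count = as.integer(ia),
             ia_ratio = unname(ratio),
             stringsAsFactors = FALSE)
}

#' Full per-genome quality report
#'
#' Combines BUSCO absences, the IA statistics on the strongest interacting
#' pairs, the number of retained OGs, and the similarity to the reference
#' species into one table (one row per species).
#'
#' @param m profile matrix.
#' @param busco named vector of BUSCO absence counts (see
#'   [load_busco_absences()]).
#' @param positives positive benchmark OG pairs.
#' @param ref_species reference interactome species id (for the distance and
#'   shared-OG columns).
#' @param strong_mode,strong_value strong-pair selection passed to
#'   [select_strong_pairs()].
#' @return data.frame, one row per species.
#' @export
genome_quality_report <- function(m, busco, positives, ref_species,
                                  strong_mode = "fraction", strong_value = 0.1) {
  strong <- select_strong_pairs(m, positives, mode = strong_mode,
                                value = strong_value)
  ia <- illogical_absence_stats(m, strong)
  simref <- similarity_to_reference(m, ref_species)
  out <- merge(ia, simref, by = "species", sort = TRUE)
  out$busco_absences <- unname(busco[out$species])
  out$retained_ogs <- as.integer(colSums(m))[match(out$species, colnames(m))]
  out[order(out$species), c("species", "busco_absences", "co_presence",
                            "co_absence", "ia_count", "ia_ratio",
                            "cosine_dist", "shared_ogs", "retained_ogs")]
}
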