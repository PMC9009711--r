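# Binary phylogenetic profiles: construction, subsetting, distances, entropy.
#
# The central object is the profile matrix: an integer 0/1 matrix with
# orthologous groups (OGs) as rows and species as columns. Entry (og, sp) = 1
# means the OG has at least one member gene annotated in that species.

#' Validate a profile matrix
#'
#' A profile matrix is an integer matrix of 0/1 values with unique, non-empty
#' OG row names and species column names.
#'
#' @param m matrix to validate.
#' @return `m`, invisibly, after validation.
#' @export
validate_profile_matrix <- function(m) {
  abort_if(!is.matrix(m), "profile matrix must be a matrix")
  abort_if(is.null(rownames(m)) || is.null(colnames(m)),
           "profile matrix must have OG rownames and species colnames")
  abort_if(anyDuplicated(rownames(m)) > 0, "duplicated OG ids in profile matrix")
  abort_if(anyDuplicated(colnames(m)) > 0, "duplicated species ids in profile matrix")
  abort_if(!all(m %in% c(0L, 1L)), "profile matrix entries must be 0 or 1")
  invisible(m)
}

#' Build a binary OG-by-species profile matrix from orthogroup memberships
#'
#' @param og_memberships named list: OG id -> named list (species -> character
#'   vector of gene ids). An OG is marked present (1) in a species when it has
#'   at least one member gene there; gene multiplicity collapses to presence.
#' @param species_order character vector fixing the column order. Species that
#'   occur in the memberships but not here are ignored with a warning.
#' @return integer 0/1 matrix, rows ordered by first appearance of OGs in
#'   `og_memberships`, columns ordered by `species_order`.
#' @export
build_profile_matrix <- function(og_memberships, species_order) {
  abort_if(length(og_memberships) == 0, "empty orthogroup membership map")
  og_ids <- names(og_memberships)
  abort_if(is.null(og_ids) || any(!nzchar(og_ids)), "orthogroup map must be named by OG id")
  dup <- og_ids[duplicated(og_ids)]
  abort_if(length(dup) > 0, "duplicate OG id(s): %s", paste(unique(dup), collapse = ", "))
  species_order <- as.character(species_order)
  abort_if(anyDuplicated(species_order) > 0, "duplicated species in species_order")

  seen_species <- unique(unlist(lapply(og_memberships, names), use.names = FALSE))
  unknown <- setdiff(seen_species, species_order)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring %d species absent from species_order: %s",
                    length(unknown), paste(unknown, collapse = ", ")),
            call. = FALSE)
  }

  m <- matrix(0L, nrow = length(og_ids), ncol = length(species_order),
              dimnames = list(og_ids, species_order))
  for (og in og_ids) {
    members <- og_memberships[[og]]
    if (length(members) == 0) next
    sp <- names(members)[lengths(members) > 0]
    sp <- intersect(sp, species_order)
    if (length(sp) > 0) m[og, sp] <- 1L
  }
  validate_profile_matrix(m)
  m
}

#' Cosine distance between two binary profiles
#'
#' Returns `1 - (a . b) / (|a| |b|)`. For binary vectors this lies in
#' `[0, 1]`: 0 for identical supports, 1 for disjoint supports.
#'
#' @param a,b binary (0/1) vectors of equal length, each with at least one 1.
#' @return numeric scalar in `[0, 1]`.
#' @export
cosine_distance <- function(a, b) {
  abort_if(length(a) != length(b), "profiles differ in length (%d vs %d)",
           length(a), length(b))
  na <- sum(a)
  nb <- sum(b)
  abort_if(na == 0 || nb == 0,
           "cosine distance undefined for an all-absent profile")
  d <- 1 - sum(a * b) / sqrt(na * nb)
  # clamp tiny negative rounding at identical profiles
  min(max(d, 0), 1)
}

#' Pairwise cosine distance between species
#'
#' Treats each species column as a binary vector over OGs and returns the
#' symmetric matrix of pairwise cosine distances (zero diagonal).
#'
#' @param m profile matrix (OGs x species).
#' @return numeric species-by-species matrix.
#' @export
species_distance_matrix <- function(m) {
  validate_profile_matrix(m)
  counts <- colSums(m)
  empty <- names(counts)[counts == 0]
  abort_if(length(empty) > 0, "species with no present OG: %s",
           paste(empty, collapse = ", "))
  cross <- crossprod(m)                       # species x species co-presence counts
  norm <- sqrt(counts)
  d <- 1 - cross / outer(norm, norm)
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  d
}

#' Shannon entropy of a profile's presence proportion
#'
#' Binary entropy of the fraction of species in which the OG is present:
#' `-f log2 f - (1-f) log2(1-f)` bits, with `0 log2 0 = 0`. High entropy
#' (near 1 bit) marks profiles with balanced presence/absence -- the
#' information-rich patterns repeated gene loss produces.
#'
#' @param p binary (0/1) vector.
#' @return entropy in bits, in `[0, 1]`.
#' @export
profile_entropy <- function(p) {
  abort_if(length(p) == 0, "empty profile")
  f <- mean(p)
  plogp <- function(x) if (x <= 0) 0 else x * log2(x)
  -plogp(f) - plogp(1 - f)
}

#' Per-species similarity to a reference species
#'
#' For each species, the cosine distance between its profile column and the
#' reference species' column, plus the number of OGs present in both.
#'
#' @param m profile matrix.
#' @param ref_species a species id present among the columns of `m`.
#' @return data.frame with columns `species`, `cosine_dist`, `shared_ogs`.
#' @export
similarity_to_reference <- function(m, ref_species) {
  validate_profile_matrix(m)
  abort_if(!ref_species %in% colnames(m), "unknown reference species '%s'", ref_species)
  ref <- m[, ref_species]
  shared <- as.integer(crossprod(m, ref))
  dist <- vapply(colnames(m), function(sp) cosine_distance(m[, sp], ref), numeric(1))
  data.frame(species = colnames(m), cosine_dist = unname(dist),
             shared_ogs = shared, stringsAsFactors = FALSE)
}

#' Drop rows that are all-absent under a species subset
#'
#' Cosine distance is undefined on a zero vector, so rows that become all-zero
#' after column selection are removed before any pair scoring; the number of
#' dropped rows is attached as attribute `dropped` and logged.
#'
#' @param m profile matrix.
#' @param species_subset optional character vector of species columns to keep.
#' @return the subset matrix with all-zero rows removed; attribute `dropped`
#'   holds the dropped OG ids.
#' @export
subset_profile_matrix <- function(m, species_subset = NULL) {
  validate_profile_matrix(m)
  if (!is.null(species_subset)) {
    species_subset <- as.character(species_subset)
    missing_sp <- setdiff(species_subset, colnames(m))
    abort_if(length(missing_sp) > 0, "species not in matrix: %s",
             paste(missing_sp, collapse = ", "))
    m <- m[, species_subset, drop = FALSE]
  }
  keep <- rowSums(m) > 0
  dropped <- rownames(m)[!keep]
  if (length(dropped) > 0) {
    message(sprintf("dropping %d OG row(s) that are all-absent under the species subset",
                    length(dropped)))
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
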