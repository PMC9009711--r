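# Readers and writers for the plain-text formats the pipeline consumes and
# emits: orthogroup tables, binary profile TSVs, species trees with
# supergroup maps, BioGRID-style TAB tables, BUSCO absence counts, gene->GO
# annotations, benchmarks, classifications and ROC summaries.

#' Read an orthogroup table (wide, Sonicparanoid/OrthoFinder style)
#'
#' First column = OG id, one column per species holding comma-separated gene
#' ids (empty = OG absent in that species).
#'
#' @param path TSV path.
#' @return named list OG -> named list (species -> gene character vector),
#'   suitable for [build_profile_matrix()].
#' @export
read_orthogroups_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(ncol(tab) < 2, "orthogroup table needs an OG column plus species columns")
  species <- names(tab)[-1]
  ogs <- as.character(tab[[1]])
  out <- lapply(seq_along(ogs), function(i) {
    row <- lapply(species, function(sp) {
      cell <- tab[[sp]][i]
      if (is.na(cell) || !nzchar(cell)) character() else
        trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(row) <- species
    row[lengths(row) > 0]
  })
  names(out) <- ogs
  out
}

#' Read a long-format gene/OG membership table
#'
#' Two (or three) columns: gene, OG id, and optionally species; without a
#' species column genes are expected as `<anything>` and the species must be
#' supplied separately when building profiles.
#'
#' @param path TSV path with header.
#' @return named character vector gene -> OG.
#' @export
read_gene_og_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 2, "long-format table needs gene and OG columns")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write / read a binary profile matrix TSV
#'
#' OG ids in the first column (`og_id`), species as header, 0/1 entries.
#'
#' @param m profile matrix.
#' @param path TSV path.
#' @export
write_profile_tsv <- function(m, path) {
  validate_profile_matrix(m)
  df <- data.frame(og_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(names(tab)[1] != "og_id", "profile TSV must start with an og_id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tab$og_id)
  validate_profile_matrix(m)
  m
}

#' Read a species tree plus supergroup mapping
#'
#' @param newick_path path to a rooted Newick tree (leaf names = species ids;
#'   internal labels ignored).
#' @param supergroup_path TSV with header and columns `species_id`,
#'   `supergroup`, `domain`.
#' @return `species_phylogeny`.
#' @export
read_species_tree <- function(newick_path, supergroup_path) {
  tree <- ape::read.tree(newick_path)
  abort_if(is.null(tree), "could not parse Newick tree from %s", newick_path)
  tab <- utils::read.delim(supergroup_path, stringsAsFactors = FALSE)
  abort_if(!all(c("species_id", "supergroup", "domain") %in% names(tab)),
           "supergroup table needs columns species_id, supergroup, domain")
  sg <- stats::setNames(tab$supergroup, tab$species_id)
  dom_tab <- unique(tab[, c("supergroup", "domain")])
  dup <- dom_tab$supergroup[duplicated(dom_tab$supergroup)]
  abort_if(length(dup) > 0, "supergroup mapped to several domains: %s",
           paste(dup, collapse = ", "))
  dom <- stats::setNames(dom_tab$domain, dom_tab$supergroup)
  species_phylogeny(tree, sg, dom)
}

#' Write the species tree and supergroup map of a phylogeny
#'
#' @param phy `species_phylogeny`.
#' @param newick_path,supergroup_path output paths.
#' @export
write_species_tree <- function(phy, newick_path, supergroup_path) {
  ape::write.tree(phy$tree, file = newick_path)
  tab <- data.frame(species_id = phy$tree$tip.label,
                    supergroup = unname(phy$supergroup_of[phy$tree$tip.label]),
                    stringsAsFactors = FALSE)
  tab$domain <- unname(phy$domain_of[tab$supergroup])
  utils::write.table(tab, supergroup_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(newick_path)
}

#' Write interaction records as a BioGRID-style TAB table
#'
#' One row per (pair, PubMed id), with BioGRID TAB 2.0 column headers, so
#' that [parse_interaction_table()] round-trips the records.
#'
#' @param records records data.frame (`gene_a`, `gene_b`, `pubmed_ids`).
#' @param path output path.
#' @param organism organism identifier written for both interactors.
#' @export
write_biogrid_tab <- function(records, path, organism = "9606") {
  n_per <- lengths(records$pubmed_ids)
  idx <- rep(seq_len(nrow(records)), n_per)
  tab <- data.frame(
    "Official Symbol Interactor A" = records$gene_a[idx],
    "Official Symbol Interactor B" = records$gene_b[idx],
    "Pubmed ID" = unlist(records$pubmed_ids, use.names = FALSE),
    "Experimental System Type" = "physical",
    "Organism Interactor A" = organism,
    "Organism Interactor B" = organism,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a BUSCO absence-count table
#' @param busco named integer vector species -> absences.
#' @param path TSV path.
#' @export
write_busco_tsv <- function(busco, path) {
  utils::write.table(data.frame(species_id = names(busco),
                                absences = unname(busco)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a two-column gene -> GO annotation table
#' @param gene_to_go data.frame with columns `gene`, `go`.
#' @param path TSV path.
#' @export
write_gene2go_tsv <- function(gene_to_go, path) {
  utils::write.table(gene_to_go[, c("gene", "go")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene2go_tsv
#' @export
read_gene2go_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 2, "gene->GO table needs two columns")
  data.frame(gene = as.character(tab[[1]]), go = as.character(tab[[2]]),
             stringsAsFactors = FALSE)
}

#' Write / read an interaction benchmark
#'
#' TSV with columns `og_a`, `og_b`, `label` (1 = positive, 0 = negative) plus
#' a JSON provenance sidecar (`<path>.json`).
#'
#' @param bench `interaction_benchmark`.
#' @param path TSV path.
#' @export
write_benchmark_tsv <- function(bench, path) {
  tab <- rbind(data.frame(og_a = bench$positives$a, og_b = bench$positives$b,
                          label = 1L),
               data.frame(og_a = bench$negatives$a, og_b = bench$negatives$b,
                          label = 0L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(provenance = bench$provenance, counts = bench$counts),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_benchmark_tsv
#' @export
read_benchmark_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(provenance = list(), counts = list())
  structure(list(
    positives = data.frame(a = tab$og_a[tab$label == 1],
                           b = tab$og_b[tab$label == 1], stringsAsFactors = FALSE),
    negatives = data.frame(a = tab$og_a[tab$label == 0],
                           b = tab$og_b[tab$label == 0], stringsAsFactors = FALSE),
    provenance = meta$provenance, counts = meta$counts),
    class = "interaction_benchmark")
}

#' Write an OG classification table
#' @param classification data.frame from [classify_ogs()].
#' @param path TSV path.
#' @export
write_classification_tsv <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ROC result (points TSV + JSON summary)
#' @param roc `roc_result`.
#' @param path TSV path for the curve points; the summary goes to
#'   `<path>.json`.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(auc = roc$auc, n_pos = roc$n_pos, n_neg = roc$n_neg,
                            dropped_pairs = roc$dropped_pairs,
                            provenance = roc$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write every input format of a synthetic world to a directory
#'
#' Emits the exact formats the pipeline reads: wide orthogroup TSV (reference
#' species carries the synthesized gene symbols, other species placeholder
#' ids), profile TSV, Newick tree + supergroup TSV, BioGRID-style TAB per
#' interactome, BUSCO TSV, gene->GO TSV, and a ground-truth JSON (modules,
#' origins, noise) for tests.
#'
#' @param world `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  m <- world$observed_matrix
  ref <- world$reference_species
  og_cells <- function(og) {
    vapply(colnames(m), function(sp) {
      if (m[og, sp] == 0L) "" else if (sp == ref) {
        paste(world$og_to_genes[[og]], collapse = ",")
      } else paste0(og, "|", sp)
    }, character(1))
  }
  wide <- t(vapply(rownames(m), og_cells, character(ncol(m))))
  utils::write.table(
    data.frame(og_id = rownames(m), wide, check.names = FALSE),
    p("orthogroups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  write_profile_tsv(m, p("profiles.tsv"))
  write_species_tree(world$phylogeny, p("species_tree.nwk"), p("supergroups.tsv"))
  write_busco_tsv(world$busco_absences, p("busco_absences.tsv"))
  write_gene2go_tsv(world$gene_to_go, p("gene2go.tsv"))
  for (label in names(world$interactomes)) {
    write_biogrid_tab(world$interactomes[[label]]$records,
                      p(sprintf("interactome_%s.tab.txt", label)))
  }
  jsonlite::write_json(
    list(modules = world$modules,
         og_origin = as.list(world$og_origin),
         noise_assignments = as.list(world$noise_assignments),
         reference_species = world$reference_species,
         depleted_species = world$depleted_species,
         retained_modules = lapply(world$interactomes, `[[`, "retained_modules")),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
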