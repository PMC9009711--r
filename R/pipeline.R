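# Orchestration of the five evaluation experiments: genome quality, genome
# diversity, single-genome influence, OG selection, and reference-interactome
# selection. Each experiment is a pure, seeded function of a prepared input
# bundle, so identical configurations reproduce identical reports.

#' Prepare the evaluation inputs from a synthetic world
#'
#' Builds every benchmark the experiments need from the world's interactomes:
#' the evidence-filtered full-reference benchmark (the "initial" setting),
#' its unfiltered counterpart (positives at any evidence level, same negative
#' definition), and the filtered benchmark of the module-depleted reference.
#' Also classifies all OGs (LECA / post-LECA) on the observed matrix.
#'
#' @param world `synthetic_world`.
#' @param min_pubs evidence threshold (default 5).
#' @param negative_ratio negatives are down-sampled to this multiple of the
#'   positive count (rank AUC only gains Monte-Carlo noise from negative
#'   down-sampling; 10x keeps null-distribution sweeps tractable).
#' @param seed seed for the negative down-sampling.
#' @return list (class `profiling_inputs`) with `matrix`, `phy`, `busco`,
#'   `benchmarks` (`filtered`, `unfiltered`, `depleted`), `partition`,
#'   `reference_species`, `gene_to_og`, `og_to_genes`, `gene_to_go`.
#' @export
profiling_inputs <- function(world, min_pubs = 5, negative_ratio = 10,
                             seed = 1L) {
  m <- suppressMessages(subset_profile_matrix(world$observed_matrix))
  attr(m, "dropped") <- NULL
  gene_to_og <- world_gene_to_og(world)

  build_bench <- function(records, min_pubs_pos, label, ref) {
    strong <- filter_by_evidence(records, min_pubs_pos)
    pos_genes <- strong[, c("gene_a", "gene_b")]
    neg_genes <- build_negative_set(records, min_pubs = min_pubs)
    npos_est <- nrow(map_to_og_pairs(pos_genes, gene_to_og))
    assemble_benchmark(pos_genes, neg_genes, gene_to_og, m,
                       max_negatives = negative_ratio * npos_est, seed = seed,
                       provenance = list(min_pubs = min_pubs_pos,
                                         reference = ref, label = label))
  }
  full <- world$interactomes$full
  depl <- world$interactomes$depleted
  benchmarks <- list(
    filtered = build_bench(full$records, min_pubs, "filtered",
                           full$reference_species),
    unfiltered = build_bench(full$records, 1, "unfiltered",
                             full$reference_species),
    depleted = build_bench(depl$records, min_pubs, "depleted",
                           depl$reference_species))

  structure(list(matrix = m, phy = world$phylogeny,
                 busco = world$busco_absences,
                 benchmarks = benchmarks,
                 partition = partition_ogs(m, world$phylogeny),
                 reference_species = world$reference_species,
                 depleted_species = world$depleted_species,
                 gene_to_og = gene_to_og,
                 og_to_genes = world$og_to_genes,
                 gene_to_go = world$gene_to_go),
            class = "profiling_inputs")
}

#' Cross-check the identifier universes of an input bundle
#'
#' Report-only: lists every mismatch between the profile matrix species, the
#' tree leaves, the supergroup map, the BUSCO table, and the benchmark OGs
#' versus the matrix rows.
#'
#' @param inputs `profiling_inputs` (or any list with the same fields).
#' @return data.frame with columns `stage`, `id` (empty when consistent).
#' @export
validate_inputs <- function(inputs) {
  mism <- list()
  note <- function(stage, ids) {
    if (length(ids) > 0) {
      mism[[length(mism) + 1]] <<- data.frame(stage = stage, id = ids,
                                              stringsAsFactors = FALSE)
    }
  }
  sp <- colnames(inputs$matrix)
  tips <- inputs$phy$tree$tip.label
  note("matrix_species_not_in_tree", setdiff(sp, tips))
  note("tree_leaves_not_in_matrix", setdiff(tips, sp))
  note("leaves_without_supergroup", setdiff(tips, names(inputs$phy$supergroup_of)))
  if (!is.null(inputs$busco)) {
    note("species_without_busco", setdiff(sp, names(inputs$busco)))
  }
  for (bn in names(inputs$benchmarks)) {
    b <- inputs$benchmarks[[bn]]
    ogs <- unique(c(b$positives$a, b$positives$b, b$negatives$a, b$negatives$b))
    note(sprintf("benchmark_%s_ogs_not_in_matrix", bn),
         setdiff(ogs, rownames(inputs$matrix)))
  }
  if (length(mism) == 0) {
    data.frame(stage = character(), id = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, mism)
  }
}

# AUC of one species selection under the initial setting: the evidence-
# filtered benchmark evaluated on the LECA-OG profiles (the initial set is
# defined over OGs assigned to LECA)
auc_of_species <- function(inputs, species, bench = "filtered") {
  evaluate_configuration(inputs$matrix, inputs$benchmarks[[bench]],
                         species_subset = species,
                         og_subset = inputs$partition$leca)$auc
}

# AUCs of a list of selection_results (species subsets)
null_aucs_species <- function(inputs, sets, bench = "filtered") {
  vapply(sets, function(s) auc_of_species(inputs, s$member_ids, bench), numeric(1))
}

experiment_report <- function(name, aucs, selections = list(),
                              null_aucs = numeric(), extra = list()) {
  structure(c(list(experiment = name, aucs = aucs,
                   null_aucs = null_aucs,
                   null_quantiles = if (length(null_aucs) > 0) {
                     stats::quantile(null_aucs, c(0.05, 0.25, 0.5, 0.75, 0.95))
                   } else numeric(),
                   selections = lapply(selections, `[[`, "member_ids")),
              extra),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment '%s'\n", x$experiment))
  for (nm in names(x$aucs)) cat(sprintf("  AUC %-16s %.4f\n", nm, x$aucs[[nm]]))
  if (length(x$null_aucs) > 0) {
    cat(sprintf("  null (n = %d): median %.4f [5%%: %.4f, 95%%: %.4f]\n",
                length(x$null_aucs), stats::median(x$null_aucs),
                x$null_quantiles[["5%"]], x$null_quantiles[["95%"]]))
  }
  invisible(x)
}

experiment_quality <- function(inputs, k = 50, n_random = 1000, seed = 1L) {
  best <- select_by_quality(inputs$busco, k, "least",
                            exclude = inputs$reference_species)
  worst <- select_by_quality(inputs$busco, k, "most",
                             exclude = inputs$reference_species)
  nulls <- random_species_sets(colnames(inputs$matrix), k, n_random, seed)
  experiment_report(
    "quality",
    aucs = list(initial = auc_of_species(inputs, NULL),
                quality_best = auc_of_species(inputs, best$member_ids),
                quality_worst = auc_of_species(inputs, worst$member_ids)),
    selections = list(quality_best = best, quality_worst = worst),
    null_aucs = null_aucs_species(inputs, nulls))
}

experiment_diversity <- function(inputs, k = 50, diverse_threshold = 0.38,
                                 similar_threshold = 0.58, auto_relax = TRUE,
                                 n_random = 1000, seed = 1L) {
  leca_m <- inputs$matrix[inputs$partition$leca, , drop = FALSE]
  d <- species_distance_matrix(leca_m)
  diverse <- select_by_diversity(d, k, "diverse", diverse_threshold, auto_relax)
  similar <- select_by_diversity(d, k, "similar", similar_threshold, auto_relax)
  nulls <- random_species_sets(colnames(inputs$matrix), k, n_random, seed)
  experiment_report(
    "diversity",
    aucs = list(initial = auc_of_species(inputs, NULL),
                diverse = auc_of_species(inputs, diverse$member_ids),
                similar = auc_of_species(inputs, similar$member_ids)),
    selections = list(diverse = diverse, similar = similar),
    null_aucs = null_aucs_species(inputs, nulls))
}

experiment_influence <- function(inputs, k = 50, n_random = 1000, seed = 1L,
                                 strong_value = 0.1) {
  influence <- leave_one_out_influence(
    inputs$matrix[inputs$partition$leca, , drop = FALSE],
    inputs$benchmarks$filtered)
  tops <- top_influencers(influence, k)
  nulls <- random_species_sets(colnames(inputs$matrix), k, n_random, seed)
  quality <- genome_quality_report(inputs$matrix, inputs$busco,
                                   inputs$benchmarks$filtered$positives,
                                   inputs$reference_species,
                                   strong_value = strong_value)
  experiment_report(
    "influence",
    aucs = list(initial = attr(influence, "auc_full"),
                advantageous = auc_of_species(inputs, tops$advantageous$member_ids),
                disadvantageous = auc_of_species(inputs, tops$disadvantageous$member_ids)),
    selections = tops,
    null_aucs = null_aucs_species(inputs, nulls),
    extra = list(influence = influence, genome_stats = quality))
}

experiment_og_selection <- function(inputs, fraction = 0.63, n_random = 1000,
                                    seed = 1L) {
  part <- inputs$partition
  nulls <- random_og_subsets(part$leca, fraction, n_random, seed)
  ev <- function(ogs) evaluate_configuration(inputs$matrix,
                                             inputs$benchmarks$filtered,
                                             og_subset = ogs)$auc
  experiment_report(
    "og_selection",
    aucs = list(leca = ev(part$leca),
                post_leca = ev(part$post_leca),
                all_ogs = ev(part$all)),
    null_aucs = vapply(nulls, function(s) ev(s$member_ids), numeric(1)),
    extra = list(partition_sizes = lapply(part, length)))
}

experiment_interactome <- function(inputs, repeats = 10, min_overlap = 3,
                                   alpha = 0.01, n_random = 1000, seed = 1L) {
  # benchmark-level contrasts are evaluated on the full observed matrix so
  # the comparison isolates the benchmark choice from OG selection
  part <- inputs$partition
  ev <- function(bench) evaluate_configuration(inputs$matrix,
                                               inputs$benchmarks[[bench]])$auc
  og_in <- function(bench) unique(c(inputs$benchmarks[[bench]]$positives$a,
                                    inputs$benchmarks[[bench]]$positives$b))
  full_ogs <- og_in("filtered")
  depl_ogs <- og_in("depleted")
  sample_ogs <- setdiff(full_ogs, depl_ogs)      # interacting OGs of the full
  population_ogs <- intersect(full_ogs, depl_ogs)  # reference only vs shared
  enr <- if (length(sample_ogs) > 0 && length(population_ogs) > 0) {
    go_enrichment(sample_ogs, population_ogs, inputs$og_to_genes,
                  inputs$gene_to_go, repeats = repeats,
                  min_overlap = min_overlap, alpha = alpha, seed = seed)
  } else NULL
  nulls <- random_og_subsets(part$leca, 0.63, n_random, seed)
  null_aucs <- vapply(nulls, function(s) {
    evaluate_configuration(inputs$matrix, inputs$benchmarks$filtered,
                           og_subset = s$member_ids)$auc
  }, numeric(1))
  experiment_report(
    "interactome_selection",
    aucs = list(filtered = ev("filtered"),
                unfiltered = ev("unfiltered"),
                depleted_reference = ev("depleted")),
    null_aucs = null_aucs,
    extra = list(enrichment = enr,
                 sample_ogs = sample_ogs, population_ogs = population_ogs))
}

#' Run one of the five evaluation experiments
#'
#' @param inputs `profiling_inputs`.
#' @param experiment one of `"quality"`, `"diversity"`, `"influence"`,
#'   `"og_selection"`, `"interactome_selection"`.
#' @param k selection size for genome experiments (default 50).
#' @param n_random size of the random null backdrop (default 1000).
#' @param seed RNG seed for the experiment's random draws.
#' @param ... passed to the specific experiment (thresholds, fraction,
#'   enrichment settings).
#' @return `experiment_report`: named AUCs, selections, null AUC vector and
#'   quantiles, plus experiment-specific extras.
#' @export
run_experiment <- function(inputs, experiment, k = 50, n_random = 1000,
                           seed = 1L, ...) {
  enabled <- c("quality", "diversity", "influence", "og_selection",
               "interactome_selection")
  abort_if(!experiment %in% enabled, "unknown experiment '%s'; available: %s",
           experiment, paste(enabled, collapse = ", "))
  switch(experiment,
         quality = experiment_quality(inputs, k, n_random, seed),
         diversity = experiment_diversity(inputs, k, n_random = n_random,
                                          seed = seed, ...),
         influence = experiment_influence(inputs, k, n_random, seed, ...),
         og_selection = experiment_og_selection(inputs, n_random = n_random,
                                                seed = seed, ...),
         interactome_selection = experiment_interactome(inputs,
                                                        n_random = n_random,
                                                        seed = seed, ...))
}

#' Run all five experiments
#'
#' @inheritParams run_experiment
#' @param experiments subset of experiment names (default: all five).
#' @return named list of `experiment_report`s.
#' @export
run_all_experiments <- function(inputs, k = 50, n_random = 1000, seed = 1L,
                                experiments = c("quality", "diversity",
                                                "influence", "og_selection",
                                                "interactome_selection")) {
  stats::setNames(lapply(experiments, function(e) {
    run_experiment(inputs, e, k = k, n_random = n_random, seed = seed)
  }), experiments)
}
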