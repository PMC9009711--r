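#!/usr/bin/env Rscript
# Genome-selection experiments on the LECA initial set: (1) quality -- the 50
# genomes with fewest/most BUSCO absences against a 200-set random backdrop;
# (2) diversity -- greedy maximally diverse / similar 50-genome sets from the
# pairwise species cosine distances; (3) influence -- leave-one-out deltas,
# the top-50 advantageous/disadvantageous sets, and the per-genome statistics
# that characterize them.

suppressPackageStartupMessages(library(phyloprof))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
n_random <- 200

world <- simulate_world(world_config(seed = seed))
inputs <- profiling_inputs(world, seed = seed)
dir.create("results", showWarnings = FALSE)

report_json <- function(rep_, path) {
  jsonlite::write_json(
    list(experiment = rep_$experiment, aucs = rep_$aucs,
         null_quantiles = as.list(rep_$null_quantiles),
         selections = rep_$selections),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

quality <- run_experiment(inputs, "quality", k = 50, n_random = n_random,
                          seed = seed)
print(quality)
report_json(quality, "results/experiment_quality.json")

diversity <- run_experiment(inputs, "diversity", k = 50, n_random = n_random,
                            seed = seed)
print(diversity)
message(sprintf("note: greedy thresholds auto-relaxed where needed"))
report_json(diversity, "results/experiment_diversity.json")

influence <- run_experiment(inputs, "influence", k = 50, n_random = n_random,
                            seed = seed)
print(influence)
report_json(influence, "results/experiment_influence.json")
utils::write.table(influence$influence, "results/influence_per_genome.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(influence$genome_stats, "results/influence_genome_stats.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

noisy <- names(which(world$noise_assignments > 0))
loo <- influence$influence
top15 <- loo$species[order(-loo$delta_auc, loo$species)][1:15]
message(sprintf("noise genomes among the top-15 disadvantageous: %d of %d",
                sum(noisy %in% top15), length(noisy)))
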