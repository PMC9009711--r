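#!/usr/bin/env Rscript
# Build the interaction benchmarks from the simulated interactomes: parse the
# records, keep pairs with five or more independent studies (positives),
# enumerate well-studied gene pairs never reported together (negatives), map
# both to OG pairs, and cross-validate every identifier universe.

suppressPackageStartupMessages(library(phyloprof))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

world <- simulate_world(world_config(seed = seed))
inputs <- profiling_inputs(world, seed = seed)

mismatches <- validate_inputs(inputs)
stopifnot(nrow(mismatches) == 0)
message("identifier universes are consistent (matrix / tree / BUSCO / benchmarks)")

dir.create("results", showWarnings = FALSE)
for (name in names(inputs$benchmarks)) {
  b <- inputs$benchmarks[[name]]
  path <- file.path("results", sprintf("benchmark_%s.tsv", name))
  write_benchmark_tsv(b, path)
  message(sprintf("%-10s %5d positives, %6d negatives -> %s",
                  name, nrow(b$positives), nrow(b$negatives), path))
}

cls <- classify_ogs(inputs$matrix, inputs$phy)
write_classification_tsv(cls, file.path("results", "og_classification.tsv"))
message(sprintf("OG classification: %d LECA, %d post-LECA (of %d)",
                sum(cls$status == "LECA"), sum(cls$status == "post-LECA"),
                nrow(cls)))

quality <- genome_quality_report(inputs$matrix, inputs$busco,
                                 inputs$benchmarks$filtered$positives,
                                 inputs$reference_species)
utils::write.table(quality, file.path("results", "genome_quality.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("per-genome quality report (BUSCO absences, illogical absences, ",
        "similarity to reference) -> results/genome_quality.tsv")
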