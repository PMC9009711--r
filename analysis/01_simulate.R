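#!/usr/bin/env Rscript
# Simulate the default synthetic world -- 80 species in 8 supergroups across
# the two eukaryotic domains, 40 co-evolving OG modules plus singletons
# evolving by Dollo loss, 10 genomes with false-absence noise, and a full
# plus a module-depleted reference interactome -- and write every input
# format the downstream analyses read.

suppressPackageStartupMessages(library(phyloprof))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

world <- simulate_world(world_config(seed = seed))
print(world)

outdir <- file.path("results", "world")
write_world(world, outdir)
message("inputs written to ", outdir, ":")
for (f in list.files(outdir)) message("  ", f)

message(sprintf("reference species: %s (noise never applied there)",
                world$reference_species))
message(sprintf("depleted reference: %s, retaining %d of %d modules",
                world$depleted_species,
                length(world$interactomes$depleted$retained_modules),
                length(world$modules)))
message(sprintf("noisy genomes (false-absence rate %.1f): %s",
                world$config$noise_rate,
                paste(names(which(world$noise_assignments > 0)),
                      collapse = ", ")))
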