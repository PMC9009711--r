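Package: phyloprof
Title: Phylogenetic Profiling Benchmarks for Eukaryotic Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary phylogenetic profiles of orthologous groups across
    eukaryotic species, classifies groups as ancestral (LECA) or lineage-specific
    via Dollo parsimony on a rooted species tree, assembles evidence-filtered
    positive and negative protein-interaction benchmarks from BioGRID-style
    tables, and quantifies how genome quality, genome diversity, single-genome
    influence, orthologous-group selection, and reference-interactome choice
    affect cosine-distance interaction-prediction AUC. Includes a synthetic-world
    generator (species tree with supergroup structure, module-correlated Dollo
    loss, per-genome false-absence noise, reference interactomes with evidence
    counts) so every analysis stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
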