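# Shared fixtures and independent oracles.

# four-leaf toy phylogeny: ((A,B),(C,D)); A,B Amorphae; C,D Diaphoretickes
toy_phylogeny <- function() {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  species_phylogeny(
    tree,
    supergroup_of = c(A = "SG1", B = "SG2", C = "SG3", D = "SG4"),
    domain_of = c(SG1 = "Amorphae", SG2 = "Amorphae",
                  SG3 = "Diaphoretickes", SG4 = "Diaphoretickes"))
}

# small fast world for unit tests; ... overrides the reduced defaults
small_world <- function(seed = 1, ...) {
  defaults <- list(
    n_species = 24, n_supergroups = 4, n_modules = 8, ogs_per_module = 5,
    n_singleton_ogs = 20, n_noise_species = 3,
    post_leca_clade_range = c(3, 12), oversplit_clade_range = c(2, 8),
    seed = seed)
  simulate_world(do.call(world_config, utils::modifyList(defaults, list(...))))
}

# memoised default worlds + inputs for the acceptance suite (criteria share
# the same seeded study conditions)
.world_bank <- new.env(parent = emptyenv())
acceptance_world <- function(seed) {
  key <- as.character(seed)
  if (is.null(.world_bank[[key]])) {
    world <- simulate_world(world_config(seed = seed))
    inputs <- suppressWarnings(profiling_inputs(world))
    .world_bank[[key]] <- list(world = world, inputs = inputs)
  }
  .world_bank[[key]]
}

# brute-force AUC oracle: direct pairwise comparison count
bf_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# brute-force Dollo oracle: minimal losses for a single gain at the MRCA of
# the present leaves, by exhaustive enumeration of internal-node states
# (1 = lineage has the gene). Valid assignments: leaves fixed, no regain
# (parent 0 => child 0), gain-node state 1. Losses = edges 1 -> 0.
bf_dollo_losses <- function(tree, present_tips) {
  tips <- tree$tip.label
  stopifnot(length(present_tips) >= 1)
  gain <- if (length(present_tips) == 1) match(present_tips, tips) else
    ape::getMRCA(tree, present_tips)
  n_tip <- length(tips)
  n_nodes <- max(tree$edge)
  state_fixed <- rep(NA, n_nodes)
  state_fixed[seq_len(n_tip)] <- tips %in% present_tips
  # nodes inside the gain clade (gain included)
  in_clade <- rep(FALSE, n_nodes)
  in_clade[gain] <- TRUE
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
      if (in_clade[p] && !in_clade[ch]) { in_clade[ch] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  free <- which(in_clade & seq_len(n_nodes) > n_tip & seq_len(n_nodes) != gain)
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    st <- state_fixed
    st[gain] <- TRUE
    if (length(free) > 0) {
      st[free] <- bitwAnd(mask, 2^(seq_along(free) - 1)) > 0
    }
    ok <- TRUE; losses <- 0
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
      if (!in_clade[ch] || p == 0) next
      if (!in_clade[p]) next
      if (!st[p] && st[ch]) { ok <- FALSE; break }   # regain forbidden
      if (st[p] && !st[ch]) losses <- losses + 1
    }
    if (ok) best <- min(best, losses)
  }
  list(gain_node = gain, loss_count = best)
}

# caterpillar and balanced newick strings for n leaves
caterpillar_newick <- function(n) {
  leaves <- LETTERS[seq_len(n)]
  s <- leaves[1]
  for (i in 2:n) s <- paste0("(", s, ",", leaves[i], ")")
  paste0(s, ";")
}
balanced_newick <- function(n) {
  leaves <- LETTERS[seq_len(n)]
  build <- function(x) {
    if (length(x) == 1) return(x)
    h <- ceiling(length(x) / 2)
    paste0("(", build(x[seq_len(h)]), ",", build(x[-seq_len(h)]), ")")
  }
  paste0(build(leaves), ";")
}

# in-memory BioGRID-style table builder
biogrid_table <- function(a, b, pubmed, type = "physical", org = "9606") {
  data.frame(`Official Symbol Interactor A` = a,
             `Official Symbol Interactor B` = b,
             `Pubmed ID` = pubmed,
             `Experimental System Type` = type,
             `Organism Interactor A` = org,
             `Organism Interactor B` = org,
             check.names = FALSE, stringsAsFactors = FALSE)
}
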