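# Synthetic worlds with known ground truth: a supergroup-structured species
# tree, Dollo-evolved OGs with module-correlated loss, per-genome
# false-absence noise, and reference interactomes with evidence counts.
#
# The generator emulates the data-generating assumptions of the eukaryotic
# profiling study: ancestral (LECA) gene modules repeatedly lost together
# along the tree, lineage-specific (post-LECA) modules gained later, noisy
# draft genomes with false absences, and a reference interactome whose
# positives live inside modules.

#' Configuration of a synthetic world
#'
#' Defaults define the study conditions used throughout the analyses:
#' 80 species in 8 supergroups (4 per eukaryotic domain), 40 co-evolving
#' modules of 8 OGs each plus 100 singleton OGs, 30% post-LECA origins,
#' per-module branch loss rates drawn from U(0.03, 0.15), within-module loss
#' correlation `rho = 0.9`, 10 noisy genomes with false-absence rate 0.3,
#' two genes per OG, and an interactome with 30% low-evidence noise pairs.
#'
#' @param n_species number of leaves.
#' @param n_supergroups number of supergroups, split evenly across the two
#'   domains (must be >= 4, >= 2 per domain).
#' @param n_modules number of co-evolving OG modules.
#' @param ogs_per_module OGs per module.
#' @param n_singleton_ogs independently evolving OGs outside any module.
#' @param fraction_post_leca fraction of modules (and of singletons) gained at
#'   a random internal non-root node instead of the root.
#' @param loss_rate per-branch loss probability; a length-2 vector is treated
#'   as a U(min, max) range drawn once per module (and per singleton), a
#'   scalar as a fixed rate.
#' @param rho within-module loss correlation in `[0, 1]`: each member OG
#'   copies the module-level loss indicator with probability `rho` and
#'   redraws independently otherwise.
#' @param n_noise_species number of genomes receiving false-absence noise.
#' @param noise_rate per-entry probability of a false 1 -> 0 flip in a noisy
#'   genome.
#' @param genes_per_og reference-species genes synthesized per OG.
#' @param noise_pair_fraction interactome noise pairs (random non-module gene
#'   pairs with low evidence), as a fraction of the true positive pairs.
#' @param low_evidence_contamination fraction of true pairs that receive a
#'   low evidence count (1-4 PubMed ids) and are therefore lost to the
#'   evidence filter.
#' @param evidence_high,evidence_low inclusive PubMed-count ranges for
#'   well-studied and poorly-studied pairs.
#' @param n_busco size of the single-copy ortholog set the BUSCO absence
#'   counts are drawn from.
#' @param busco_base_rate,busco_noise_coef BUSCO absence probability is
#'   `busco_base_rate + busco_noise_coef * noise_rate(species)`.
#' @param post_leca_clade_range admissible clade sizes (leaves) for post-LECA
#'   origin nodes.
#' @param n_post_leca_origins number of distinct origin nodes shared by the
#'   post-LECA OGs: lineage-specific families concentrate on a few major
#'   lineages rather than scattering over every internal node.
#' @param post_leca_loss_scale multiplier on the loss rate of post-LECA OGs
#'   (< 1: lineage-specific families show less loss than ancestral ones, so
#'   their profiles carry less information).
#' @param deep_clade_cutoff,deep_loss_scale loss events on edges whose child
#'   clade holds at least `deep_clade_cutoff` (fraction) of all species have
#'   their probability multiplied by `deep_loss_scale`: entire ancient
#'   mega-clades rarely lose an ancestral complex outright, losses accumulate
#'   along shallow lineages.
#' @param oversplit_fraction fraction of ancestral-module member OGs whose
#'   observed profile is truncated to an arbitrary clade, emulating orthology
#'   oversplitting: a truly ancestral gene whose inferred OG looks
#'   artifactually lineage-specific while still interacting with its
#'   ancestral module partners.
#' @param oversplit_clade_range admissible clade sizes (leaves) for the
#'   oversplit truncation clades.
#' @param n_background_go number of non-module background GO terms.
#' @param background_go_rate fraction of genes annotated with each background
#'   term.
#' @param retained_module_fraction module fraction retained by the depleted
#'   ("yeast-like") reference interactome.
#' @param seed RNG seed for the whole world.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_species = 80, n_supergroups = 8, n_modules = 40,
                         ogs_per_module = 8, n_singleton_ogs = 100,
                         fraction_post_leca = 0.3, loss_rate = c(0.03, 0.15),
                         rho = 0.9, n_noise_species = 10, noise_rate = 0.3,
                         genes_per_og = 2, noise_pair_fraction = 0.3,
                         low_evidence_contamination = 0.1,
                         evidence_high = c(5, 20), evidence_low = c(1, 4),
                         n_busco = 303, busco_base_rate = 0.02,
                         busco_noise_coef = 0.6,
                         post_leca_clade_range = c(8, 32),
                         n_post_leca_origins = 3, post_leca_loss_scale = 0.25,
                         deep_clade_cutoff = 0.25, deep_loss_scale = 0.2,
                         oversplit_fraction = 0.2,
                         oversplit_clade_range = c(4, 24),
                         n_background_go = 30, background_go_rate = 0.05,
                         retained_module_fraction = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  abort_if(n_species < 4, "need at least 4 species")
  abort_if(n_supergroups < 4 || n_supergroups %% 2 != 0,
           "n_supergroups must be an even number >= 4 (>= 2 per domain)")
  abort_if(n_supergroups > n_species, "more supergroups than species")
  abort_if(rho < 0 || rho > 1, "rho must be in [0, 1]")
  abort_if(noise_rate < 0 || noise_rate > 1, "noise_rate must be in [0, 1]")
  abort_if(n_noise_species > n_species, "more noisy species than species")
  abort_if(fraction_post_leca < 0 || fraction_post_leca > 1,
           "fraction_post_leca must be in [0, 1]")
  abort_if(retained_module_fraction <= 0 || retained_module_fraction > 1,
           "retained_module_fraction must be in (0, 1]")
  structure(cfg, class = "world_config")
}

# random binary newick over a leaf set (uses the active RNG stream)
random_clade_newick <- function(leaves) {
  if (length(leaves) == 1) return(leaves)
  perm <- sample(leaves)
  cut <- if (length(leaves) == 2) 1 else sample(length(leaves) - 1, 1)
  left <- random_clade_newick(perm[seq_len(cut)])
  right <- random_clade_newick(perm[-seq_len(cut)])
  paste0("(", left, ",", right, ")")
}

random_join_newick <- function(parts) {
  while (length(parts) > 1) {
    pick <- sample(length(parts), 2)
    joined <- paste0("(", parts[pick[1]], ",", parts[pick[2]], ")")
    parts <- c(parts[-pick], joined)
  }
  parts
}

#' Simulate a supergroup-structured species phylogeny
#'
#' Random rooted binary tree whose first split separates the two eukaryotic
#' domains; leaves are partitioned into monophyletic supergroups, half per
#' domain.
#'
#' @param cfg `world_config`.
#' @return `species_phylogeny`.
#' @export
simulate_phylogeny <- function(cfg) {
  withr::with_seed(cfg$seed, {
    n_sg <- cfg$n_supergroups
    sizes <- rep(cfg$n_species %/% n_sg, n_sg)
    extra <- cfg$n_species %% n_sg
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    abort_if(any(sizes < 1), "supergroup split infeasible for %d species / %d supergroups",
             cfg$n_species, n_sg)
    species <- sprintf("sp%03d", seq_len(cfg$n_species))
    sg_names <- sprintf("SG%02d", seq_len(n_sg))
    sg_of_leaf <- rep(sg_names, times = sizes)
    names(sg_of_leaf) <- species
    domain_of <- stats::setNames(
      rep(c("Amorphae", "Diaphoretickes"), each = n_sg / 2), sg_names)

    clades <- vapply(sg_names, function(sg) {
      random_clade_newick(species[sg_of_leaf == sg])
    }, character(1))
    left <- random_join_newick(clades[domain_of[sg_names] == "Amorphae"])
    right <- random_join_newick(clades[domain_of[sg_names] == "Diaphoretickes"])
    tree <- ape::read.tree(text = paste0("(", left, ",", right, ");"))
    species_phylogeny(tree, sg_of_leaf, domain_of)
  })
}

# clade (tip-count) size of every node
clade_sizes <- function(tree) {
  present_below_counts(tree, rep(TRUE, length(tree$tip.label)))
}

#' Simulate Dollo-evolving OG profiles along a phylogeny
#'
#' LECA OGs originate at the root; post-LECA OGs at internal non-root nodes
#' (clade size within `cfg$post_leca_clade_range`) drawn from the ancestors
#' of the reference species -- the benchmark can only contain families with
#' reference-genome members, so lineage innovations that matter are the ones
#' on the reference path. On every branch each module draws a loss indicator
#' with its per-module loss rate; each member OG copies it with probability
#' `rho` and redraws independently otherwise. A lost OG stays absent in the
#' whole subtree (single gain, no regain). Singleton OGs evolve
#' independently. OGs (and modules) that lose all species are dropped, with
#' the count in attribute `n_extinct`.
#'
#' @param phy `species_phylogeny`.
#' @param cfg `world_config`.
#' @param reference_species leaf whose ancestor path hosts the post-LECA
#'   origins and oversplit truncations (default: first tip label).
#' @return list: `true_matrix` (OG x species 0/1), `og_origin` (named node-id
#'   vector), `modules` (module id -> OG ids), `og_module` (named; NA for
#'   singletons), `loss_rate_of` (named per-OG rate).
#' @export
simulate_profiles <- function(phy, cfg,
                              reference_species = phy$tree$tip.label[1]) {
  tree <- ape::reorder.phylo(phy$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  root <- n_tip + 1L

  n_mod_og <- cfg$n_modules * cfg$ogs_per_module
  n_og <- n_mod_og + cfg$n_singleton_ogs
  og_ids <- sprintf("OG%04d", seq_len(n_og))
  module_ids <- sprintf("M%02d", seq_len(cfg$n_modules))
  og_module <- c(rep(seq_len(cfg$n_modules), each = cfg$ogs_per_module),
                 rep(NA_integer_, cfg$n_singleton_ogs))

  rate_range <- if (length(cfg$loss_rate) == 1) rep(cfg$loss_rate, 2) else cfg$loss_rate

  withr::with_seed(cfg$seed + 1L, {
    module_rate <- stats::runif(cfg$n_modules, rate_range[1], rate_range[2])
    singleton_rate <- stats::runif(cfg$n_singleton_ogs, rate_range[1], rate_range[2])

    # post-LECA origins: ancestors of the reference species (innovations off
    # the reference path would not contribute reference genes to a benchmark)
    sizes <- clade_sizes(tree)
    ref_tip <- match(reference_species, tree$tip.label)
    abort_if(is.na(ref_tip), "unknown reference species '%s'", reference_species)
    parent_of <- integer(n_nodes)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    ref_path <- integer()
    v <- ref_tip
    while (v != root) {
      v <- parent_of[v]
      ref_path <- c(ref_path, v)
    }
    candidates <- setdiff(ref_path[sizes[ref_path] >= cfg$post_leca_clade_range[1] &
                                     sizes[ref_path] <= cfg$post_leca_clade_range[2]],
                          root)
    abort_if(length(candidates) == 0,
             "no reference-path node with clade size in [%d, %d] for post-LECA origins",
             cfg$post_leca_clade_range[1], cfg$post_leca_clade_range[2])
    n_post_mod <- round(cfg$fraction_post_leca * cfg$n_modules)
    n_post_sing <- round(cfg$fraction_post_leca * cfg$n_singleton_ogs)
    post_modules <- if (n_post_mod > 0) {
      sort(sample(cfg$n_modules, n_post_mod))
    } else integer()
    # lineage-specific families concentrate on a few shared origin lineages
    origin_pool <- candidates[sample.int(length(candidates),
                                         min(cfg$n_post_leca_origins,
                                             length(candidates)))]
    pick_origin <- function(n) {
      origin_pool[sample.int(length(origin_pool), n, replace = TRUE)]
    }
    module_origin <- rep(root, cfg$n_modules)
    module_origin[post_modules] <- pick_origin(n_post_mod)
    singleton_origin <- rep(root, cfg$n_singleton_ogs)
    post_sing <- if (n_post_sing > 0) sort(sample(cfg$n_singleton_ogs, n_post_sing)) else integer()
    singleton_origin[post_sing] <- pick_origin(n_post_sing)
    og_origin <- c(module_origin[og_module[seq_len(n_mod_og)]], singleton_origin)

    # complexes accrete subunits over time: each member of a lineage-specific
    # module draws its own origin along the reference path
    post_og_idx <- which(og_module %in% post_modules)
    og_origin[post_og_idx] <- pick_origin(length(post_og_idx))

    # lineage-specific families lose less than ancestral ones
    module_rate[post_modules] <- module_rate[post_modules] * cfg$post_leca_loss_scale
    singleton_rate[post_sing] <- singleton_rate[post_sing] * cfg$post_leca_loss_scale
    og_rate <- ifelse(is.na(og_module), NA, module_rate[og_module])
    og_rate[is.na(og_rate)] <- singleton_rate

    # ancient mega-clades rarely lose a complex outright
    edge_scale <- ifelse(sizes[tree$edge[, 2]] >=
                           ceiling(cfg$deep_clade_cutoff * n_tip),
                         cfg$deep_loss_scale, 1)

    state <- matrix(FALSE, n_nodes, n_og)
    state[root, og_origin == root] <- TRUE
    is_module_og <- !is.na(og_module)
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]
      ch <- tree$edge[i, 2]
      z_mod <- stats::runif(cfg$n_modules) < module_rate * edge_scale[i]
      copy <- stats::runif(n_og) < cfg$rho
      indep <- stats::runif(n_og) < og_rate * edge_scale[i]
      loss <- indep
      use_mod <- is_module_og & copy
      loss[use_mod] <- z_mod[og_module[use_mod]]
      state[ch, ] <- state[p, ] & !loss
      born_here <- og_origin == ch
      if (any(born_here)) state[ch, born_here] <- TRUE
    }

    # orthology oversplitting: some ancestral-module members are observed as
    # an artifactually lineage-restricted fragment (profile truncated to a
    # clade); their recorded origin moves to the truncation node. Unlike the
    # genuine lineage innovations, the truncation clade is arbitrary -- an
    # inference artifact, not an innovation hotspot.
    leca_module_ogs <- which(is_module_og & og_origin == root)
    n_oversplit <- round(cfg$oversplit_fraction * length(leca_module_ogs))
    if (n_oversplit > 0) {
      oversplit <- sort(sample(leca_module_ogs, n_oversplit))
      trunc_pool <- setdiff(
        ref_path[sizes[ref_path] >= cfg$oversplit_clade_range[1] &
                   sizes[ref_path] <= cfg$oversplit_clade_range[2]], root)
      if (length(trunc_pool) == 0) trunc_pool <- candidates
      trunc_node <- trunc_pool[sample.int(length(trunc_pool), n_oversplit,
                                          replace = TRUE)]
      kids <- tree_children(tree)
      for (j in seq_along(oversplit)) {
        og <- oversplit[j]
        outside <- setdiff(seq_len(n_tip),
                           node_tip_ids(tree, trunc_node[j], kids))
        state[outside, og] <- FALSE
        og_origin[og] <- trunc_node[j]
      }
    }
  })

  true_matrix <- t(state[seq_len(n_tip), , drop = FALSE]) * 1L
  storage.mode(true_matrix) <- "integer"
  dimnames(true_matrix) <- list(og_ids, tree$tip.label)
  true_matrix <- true_matrix[, phy$tree$tip.label, drop = FALSE]

  alive <- rowSums(true_matrix) > 0
  n_extinct <- sum(!alive)
  true_matrix <- true_matrix[alive, , drop = FALSE]
  og_ids <- og_ids[alive]
  og_origin <- stats::setNames(og_origin[alive], og_ids)
  og_module_kept <- og_module[alive]
  modules <- lapply(seq_len(cfg$n_modules), function(mi) {
    og_ids[!is.na(og_module_kept) & og_module_kept == mi]
  })
  names(modules) <- module_ids
  modules <- modules[lengths(modules) > 0]

  out <- list(true_matrix = true_matrix,
              og_origin = og_origin,
              modules = modules,
              og_module = stats::setNames(
                ifelse(is.na(og_module_kept), NA_character_,
                       module_ids[og_module_kept]), og_ids),
              loss_rate_of = stats::setNames(og_rate[alive], og_ids))
  attr(out, "n_extinct") <- n_extinct
  out
}

#' Inject per-genome false-absence noise
#'
#' In each designated noisy species every present entry flips to absent
#' independently with probability `rate`; there are no false presences.
#'
#' @param m true profile matrix.
#' @param noise_species character vector of species receiving noise.
#' @param rate false-absence probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return list: `observed_matrix`, `noise_assignments` (named per-species
#'   rate vector, 0 for clean genomes), `n_flips` (named flip counts).
#' @export
add_quality_noise <- function(m, noise_species, rate, seed = 1L) {
  validate_profile_matrix(m)
  missing_sp <- setdiff(noise_species, colnames(m))
  abort_if(length(missing_sp) > 0, "noise species not in matrix: %s",
           paste(missing_sp, collapse = ", "))
  obs <- m
  flips <- stats::setNames(integer(length(colnames(m))), colnames(m))
  withr::with_seed(seed, {
    for (sp in noise_species) {
      present <- which(obs[, sp] == 1L)
      flip <- present[stats::runif(length(present)) < rate]
      obs[flip, sp] <- 0L
      flips[sp] <- length(flip)
    }
  })
  rates <- stats::setNames(rep(0, ncol(m)), colnames(m))
  rates[noise_species] <- rate
  list(observed_matrix = obs, noise_assignments = rates, n_flips = flips)
}

#' Simulate a reference interactome with evidence counts
#'
#' True positive pairs are all between-OG gene pairs inside modules retained
#' by the reference species; modules are ranked by how completely the
#' reference retains them (ties by global prevalence), and the top
#' `retained_module_fraction` are kept -- a depleted ("yeast-like") reference
#' with fraction < 1 drops the modules most lost in its lineage. Evidence
#' counts follow a two-component model: well-studied pairs draw
#' `evidence_high` PubMed ids, a `low_evidence_contamination` fraction of
#' true pairs and all noise pairs (random non-module gene pairs) draw
#' `evidence_low`.
#'
#' @param true_matrix noise-free profile matrix.
#' @param modules module id -> OG id list.
#' @param og_to_genes named list: OG -> genes.
#' @param reference_species leaf id of the reference organism.
#' @param retained_module_fraction fraction of modules retained, in (0, 1].
#' @param cfg `world_config`.
#' @param seed RNG seed.
#' @return list: `records` (parsed-form data.frame: `gene_a`, `gene_b`,
#'   `pubmed_ids`, `n_pubs`), `true_gene_pairs`, `retained_modules`,
#'   `reference_species`.
#' @export
simulate_interactome <- function(true_matrix, modules, og_to_genes,
                                 reference_species, retained_module_fraction,
                                 cfg, seed = 1L) {
  abort_if(!reference_species %in% colnames(true_matrix),
           "unknown reference species '%s'", reference_species)
  ref_frac <- vapply(modules, function(ogs) {
    mean(true_matrix[ogs, reference_species] == 1L)
  }, numeric(1))
  abort_if(all(ref_frac == 0), "reference species '%s' lacks all modules",
           reference_species)
  prevalence <- vapply(modules, function(ogs) {
    mean(true_matrix[ogs, , drop = FALSE])
  }, numeric(1))
  ord <- order(-ref_frac, -prevalence, names(modules))
  n_keep <- max(1L, round(retained_module_fraction * length(modules)))
  retained <- sort(names(modules)[ord][seq_len(n_keep)])

  gene_og <- rep(names(og_to_genes), lengths(og_to_genes))
  names(gene_og) <- unlist(og_to_genes, use.names = FALSE)

  true_pairs <- do.call(rbind, lapply(retained, function(mid) {
    genes <- unlist(og_to_genes[modules[[mid]]], use.names = FALSE)
    if (length(genes) < 2) return(NULL)
    p <- all_unordered_pairs(genes)
    p[gene_og[p$a] != gene_og[p$b], , drop = FALSE]   # between-OG pairs only
  }))
  true_pairs <- order_pairs(true_pairs[!duplicated(pair_key(true_pairs$a, true_pairs$b)), ])
  rownames(true_pairs) <- NULL

  n_true <- nrow(true_pairs)
  n_noise <- round(cfg$noise_pair_fraction * n_true)
  all_genes <- names(gene_og)
  true_key <- pair_key(true_pairs$a, true_pairs$b)

  withr::with_seed(seed, {
    high <- stats::runif(n_true) >= cfg$low_evidence_contamination
    n_pubs_true <- ifelse(
      high,
      sample(seq(cfg$evidence_high[1], cfg$evidence_high[2]), n_true, replace = TRUE),
      sample(seq(cfg$evidence_low[1], cfg$evidence_low[2]), n_true, replace = TRUE))

    noise <- data.frame(a = character(), b = character())
    if (n_noise > 0) {
      seen <- character()
      while (nrow(noise) < n_noise) {
        need <- (n_noise - nrow(noise)) * 2 + 10
        ga <- sample(all_genes, need, replace = TRUE)
        gb <- sample(all_genes, need, replace = TRUE)
        cand <- canonical_pairs(ga, gb)
        key <- pair_key(cand$a, cand$b)
        ok <- cand$a != cand$b & gene_og[cand$a] != gene_og[cand$b] &
          !key %in% true_key & !key %in% seen & !duplicated(key)
        # cross-module only: random pairs between genes of different modules
        cand <- cand[ok, , drop = FALSE]
        seen <- c(seen, key[ok])
        noise <- rbind(noise, cand)
      }
      noise <- noise[seq_len(n_noise), , drop = FALSE]
    }
    n_pubs_noise <- if (n_noise > 0) {
      sample(seq(cfg$evidence_low[1], cfg$evidence_low[2]), n_noise, replace = TRUE)
    } else integer()
  })

  rec <- rbind(
    data.frame(gene_a = true_pairs$a, gene_b = true_pairs$b,
               n_pubs = as.integer(n_pubs_true), stringsAsFactors = FALSE),
    if (n_noise > 0) data.frame(gene_a = noise$a, gene_b = noise$b,
                                n_pubs = as.integer(n_pubs_noise),
                                stringsAsFactors = FALSE))
  rec <- rec[order(rec$gene_a, rec$gene_b), , drop = FALSE]
  rownames(rec) <- NULL
  total <- sum(rec$n_pubs)
  ids <- sprintf("PMID%07d", seq_len(total))
  rec$pubmed_ids <- split(ids, rep(seq_len(nrow(rec)), rec$n_pubs))
  rec <- rec[, c("gene_a", "gene_b", "pubmed_ids", "n_pubs")]

  list(records = rec, true_gene_pairs = true_pairs,
       retained_modules = retained, reference_species = reference_species)
}

#' Simulate a complete synthetic world
#'
#' Chains [simulate_phylogeny()], [simulate_profiles()],
#' [add_quality_noise()] and [simulate_interactome()] (a full reference and a
#' module-depleted one), synthesizes per-OG genes, per-species BUSCO absence
#' counts (correlated with the injected noise), and GO annotations (one term
#' per module annotating all member genes, plus random background terms).
#'
#' The full ("human-like") reference is a designated leaf whose ancestor path
#' hosts the lineage innovations; the depleted ("yeast-like") reference is
#' the species retaining the fewest module OGs. Noise is never assigned to
#' the full reference.
#'
#' @param cfg `world_config`.
#' @return object of class `synthetic_world`.
#' @export
simulate_world <- function(cfg = world_config()) {
  phy <- simulate_phylogeny(cfg)
  reference_species <- phy$tree$tip.label[1]
  prof <- simulate_profiles(phy, cfg, reference_species)
  true_matrix <- prof$true_matrix

  module_ogs <- unlist(prof$modules, use.names = FALSE)
  module_presence <- colSums(true_matrix[module_ogs, , drop = FALSE])
  depleted_species <- names(which.min(
    module_presence[setdiff(names(module_presence), reference_species)]))

  withr::with_seed(cfg$seed + 2L, {
    noise_species <- sample(setdiff(colnames(true_matrix), reference_species),
                            cfg$n_noise_species)
  })
  noise <- add_quality_noise(true_matrix, noise_species, cfg$noise_rate,
                             seed = cfg$seed + 3L)

  withr::with_seed(cfg$seed + 4L, {
    rate <- cfg$busco_base_rate + cfg$busco_noise_coef * noise$noise_assignments
    busco <- stats::setNames(
      stats::rbinom(ncol(true_matrix), cfg$n_busco, rate), colnames(true_matrix))
  })

  og_ids <- rownames(true_matrix)
  og_to_genes <- stats::setNames(lapply(og_ids, function(og) {
    sprintf("%s_g%d", og, seq_len(cfg$genes_per_og))
  }), og_ids)

  interactomes <- list(
    full = simulate_interactome(true_matrix, prof$modules, og_to_genes,
                                reference_species, 1, cfg,
                                seed = cfg$seed + 5L),
    depleted = simulate_interactome(true_matrix, prof$modules, og_to_genes,
                                    depleted_species,
                                    cfg$retained_module_fraction, cfg,
                                    seed = cfg$seed + 6L))

  all_genes <- unlist(og_to_genes, use.names = FALSE)
  module_go <- do.call(rbind, lapply(names(prof$modules), function(mid) {
    genes <- unlist(og_to_genes[prof$modules[[mid]]], use.names = FALSE)
    data.frame(gene = genes, go = sprintf("GO:MOD%s", mid),
               stringsAsFactors = FALSE)
  }))
  background_go <- withr::with_seed(cfg$seed + 7L, {
    do.call(rbind, lapply(seq_len(cfg$n_background_go), function(i) {
      genes <- sample(all_genes, max(1L, round(cfg$background_go_rate *
                                                 length(all_genes))))
      data.frame(gene = genes, go = sprintf("GO:BG%04d", i),
                 stringsAsFactors = FALSE)
    }))
  })
  gene_to_go <- rbind(module_go, background_go)
  gene_to_go <- gene_to_go[order(gene_to_go$gene, gene_to_go$go), ]
  rownames(gene_to_go) <- NULL

  structure(list(config = cfg,
                 phylogeny = phy,
                 modules = prof$modules,
                 og_module = prof$og_module,
                 og_origin = prof$og_origin,
                 loss_rate_of = prof$loss_rate_of,
                 true_matrix = true_matrix,
                 observed_matrix = noise$observed_matrix,
                 noise_assignments = noise$noise_assignments,
                 noise_flips = noise$n_flips,
                 busco_absences = busco,
                 reference_species = reference_species,
                 depleted_species = depleted_species,
                 og_to_genes = og_to_genes,
                 gene_to_go = gene_to_go,
                 interactomes = interactomes),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic world: %d species, %d OGs (%d modules), ",
                     "reference '%s', depleted reference '%s'\n"),
              ncol(x$true_matrix), nrow(x$true_matrix), length(x$modules),
              x$reference_species, x$depleted_species))
  invisible(x)
}

#' Gene -> OG lookup vector of a synthetic world
#' @param world `synthetic_world`.
#' @return named character vector: gene -> OG id.
#' @export
world_gene_to_og <- function(world) {
  g <- rep(names(world$og_to_genes), lengths(world$og_to_genes))
  stats::setNames(g, unlist(world$og_to_genes, use.names = FALSE))
}
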