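# Dollo-parsimony gain/loss reconstruction and LECA classification.
#
# Under Dollo parsimony a gene family is gained exactly once; the gain is
# placed at the most recent common ancestor (MRCA) of all species carrying the
# family, and losses are then the minimal set of loss events explaining the
# absences -- one event per maximal all-absent subtree below the gain node.

#' Construct a species phylogeny with supergroup and domain annotation
#'
#' @param tree rooted `ape::phylo` tree with uniquely named leaves
#'   (multifurcations allowed).
#' @param supergroup_of named character vector: species id -> supergroup.
#' @param domain_of named character vector: supergroup -> domain; domains must
#'   be exactly the two eukaryotic domains `"Amorphae"` and `"Diaphoretickes"`.
#' @return object of class `species_phylogeny`.
#' @export
species_phylogeny <- function(tree, supergroup_of, domain_of) {
  abort_if(!inherits(tree, "phylo"), "tree must be an ape 'phylo' object")
  abort_if(anyDuplicated(tree$tip.label) > 0, "tree leaves must be uniquely named")
  missing_sg <- setdiff(tree$tip.label, names(supergroup_of))
  abort_if(length(missing_sg) > 0, "leaves without a supergroup: %s",
           paste(utils::head(missing_sg, 5), collapse = ", "))
  sgs <- unique(unname(supergroup_of[tree$tip.label]))
  missing_dom <- setdiff(sgs, names(domain_of))
  abort_if(length(missing_dom) > 0, "supergroups without a domain: %s",
           paste(missing_dom, collapse = ", "))
  doms <- unique(unname(domain_of[sgs]))
  abort_if(!setequal(doms, c("Amorphae", "Diaphoretickes")),
           "both domains (Amorphae, Diaphoretickes) must be represented; found: %s",
           paste(doms, collapse = ", "))
  structure(list(tree = tree,
                 supergroup_of = supergroup_of[tree$tip.label],
                 domain_of = domain_of[sgs]),
            class = "species_phylogeny")
}

#' @export
print.species_phylogeny <- function(x, ...) {
  cat(sprintf("species phylogeny: %d leaves, %d supergroups, 2 domains\n",
              length(x$tree$tip.label), length(unique(x$supergroup_of))))
  invisible(x)
}

# children adjacency list indexed by node id (tips 1..n, internals n+1..)
tree_children <- function(tree) {
  n_nodes <- max(tree$edge)
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

# tip ids (indices) below a node, iterative descent
node_tip_ids <- function(tree, node, kids = tree_children(tree)) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  tips <- integer()
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    for (ch in kids[[v]]) {
      if (ch <= n_tip) tips <- c(tips, ch) else stack <- c(stack, ch)
    }
  }
  tips
}

# number of present leaves below (and including) each node, postorder
present_below_counts <- function(tree, present_tips) {
  n_tip <- length(tree$tip.label)
  counts <- numeric(max(tree$edge))
  counts[seq_len(n_tip)] <- as.numeric(present_tips)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    counts[edges[i, 1]] <- counts[edges[i, 1]] + counts[edges[i, 2]]
  }
  counts
}

#' Dollo-parsimony reconstruction of a single OG
#'
#' Places the single gain at the MRCA of all present leaves and counts the
#' minimal number of loss events: one per child edge below the gain node whose
#' subtree contains no present leaf while the parent lineage is inferred
#' present (maximal all-absent subtrees).
#'
#' @param phy `species_phylogeny`.
#' @param presence named binary vector over the tree's leaves (1 = present).
#' @return list with `gain_node` (node id; tip id when a single leaf is
#'   present), `gain_label` (tip label or `"node<N>"`), `loss_count`.
#' @export
dollo_reconstruct <- function(phy, presence) {
  tree <- phy$tree
  tips <- tree$tip.label
  abort_if(is.null(names(presence)) || !all(tips %in% names(presence)),
           "presence vector must be named by tree leaves")
  pres <- presence[tips] > 0
  present_tips <- tips[pres]
  abort_if(length(present_tips) == 0,
           "all-absent profile: Dollo gain cannot be placed")
  n_tip <- length(tips)

  if (length(present_tips) == 1) {
    gain <- match(present_tips, tips)
    return(list(gain_node = gain, gain_label = tips[gain], loss_count = 0L))
  }
  gain <- ape::getMRCA(tree, present_tips)
  counts <- present_below_counts(tree, pres)
  kids <- tree_children(tree)
  losses <- 0L
  stack <- gain
  while (length(stack) > 0) {
    node <- stack[[1]]
    stack <- stack[-1]
    for (ch in kids[[node]]) {
      if (counts[ch] == 0) {
        losses <- losses + 1L            # maximal all-absent subtree
      } else if (ch > n_tip) {
        stack <- c(stack, ch)
      }
    }
  }
  label <- if (gain <= n_tip) tips[gain] else paste0("node", gain)
  list(gain_node = gain, gain_label = label, loss_count = losses)
}

#' Classify one OG as LECA or post-LECA
#'
#' An OG is assigned to the Last Eukaryotic Common Ancestor when its present
#' species cover at least three supergroups and those supergroups span both
#' domains (at least one Amorphae and one Diaphoretickes supergroup);
#' otherwise it is post-LECA. The Dollo gain node and loss count are reported
#' descriptively alongside.
#'
#' @inheritParams dollo_reconstruct
#' @param og_id optional identifier stored in the result.
#' @return list with `og_id`, `status` (`"LECA"`/`"post-LECA"`),
#'   `gain_node`, `gain_label`, `loss_count`, `supergroups_present`.
#' @export
classify_leca <- function(phy, presence, og_id = NA_character_) {
  rec <- dollo_reconstruct(phy, presence)
  tips <- phy$tree$tip.label
  present_tips <- tips[presence[tips] > 0]
  sgs <- unique(unname(phy$supergroup_of[present_tips]))
  doms <- unique(unname(phy$domain_of[sgs]))
  is_leca <- length(sgs) >= 3 &&
    all(c("Amorphae", "Diaphoretickes") %in% doms)
  list(og_id = og_id,
       status = if (is_leca) "LECA" else "post-LECA",
       gain_node = rec$gain_node, gain_label = rec$gain_label,
       loss_count = rec$loss_count,
       supergroups_present = sgs)
}

#' Classify every OG of a profile matrix
#'
#' @param m profile matrix; columns must match the phylogeny's leaves.
#' @param phy `species_phylogeny`.
#' @return data.frame with one row per OG: `og_id`, `status`, `gain_label`,
#'   `loss_count`, `n_supergroups`.
#' @export
classify_ogs <- function(m, phy) {
  validate_profile_matrix(m)
  abort_if(!setequal(colnames(m), phy$tree$tip.label),
           "matrix species and tree leaves differ")
  rows <- lapply(rownames(m), function(og) {
    cls <- classify_leca(phy, m[og, ], og_id = og)
    data.frame(og_id = og, status = cls$status, gain_label = cls$gain_label,
               loss_count = cls$loss_count,
               n_supergroups = length(cls$supergroups_present),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partition OGs into LECA, post-LECA and all sets
#'
#' @inheritParams classify_ogs
#' @return list with character vectors `leca`, `post_leca`, `all`
#'   (`leca` and `post_leca` are disjoint and union to `all`).
#' @export
partition_ogs <- function(m, phy) {
  cls <- classify_ogs(m, phy)
  list(leca = cls$og_id[cls$status == "LECA"],
       post_leca = cls$og_id[cls$status == "post-LECA"],
       all = cls$og_id)
}
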