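test_that("species phylogeny validation enforces the annotation invariants", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(species_phylogeny(tree, c(A = "SG1"), c(SG1 = "Amorphae")),
               "without a supergroup")
  sg <- c(A = "SG1", B = "SG1", C = "SG2", D = "SG2")
  expect_error(
    species_phylogeny(tree, sg, c(SG1 = "Amorphae", SG2 = "Amorphae")),
    "both domains")
  phy <- species_phylogeny(tree, sg, c(SG1 = "Amorphae", SG2 = "Diaphoretickes"))
  expect_s3_class(phy, "species_phylogeny")
})

test_that("Dollo reconstruction matches the worked four-leaf examples", {
  phy <- toy_phylogeny()
  all_present <- c(A = 1, B = 1, C = 1, D = 1)
  rec <- dollo_reconstruct(phy, all_present)
  expect_equal(rec$gain_node, 5L)          # root of a 4-leaf tree
  expect_equal(rec$loss_count, 0L)

  rec2 <- dollo_reconstruct(phy, c(A = 1, B = 1, C = 1, D = 0))
  expect_equal(rec2$gain_node, 5L)
  expect_equal(rec2$loss_count, 1L)        # single loss on the edge to D

  rec3 <- dollo_reconstruct(phy, c(A = 1, B = 0, C = 0, D = 0))
  expect_equal(rec3$gain_label, "A")
  expect_equal(rec3$loss_count, 0L)

  expect_error(dollo_reconstruct(phy, c(A = 0, B = 0, C = 0, D = 0)),
               "all-absent")
})

test_that("Dollo handles multifurcations, counting each child edge", {
  tree <- ape::read.tree(text = "(A,B,C,(D,E));")
  phy <- species_phylogeny(
    tree,
    c(A = "SG1", B = "SG1", C = "SG2", D = "SG3", E = "SG3"),
    c(SG1 = "Amorphae", SG2 = "Amorphae", SG3 = "Diaphoretickes"))
  rec <- dollo_reconstruct(phy, c(A = 1, B = 0, C = 0, D = 1, E = 0))
  expect_equal(rec$gain_node, 6L)          # root
  expect_equal(rec$loss_count, 3L)         # edges to B, C and E
})

test_that("loss counts equal exhaustive minimisation on all small trees", {
  shapes <- c(lapply(2:6, caterpillar_newick), lapply(4:6, balanced_newick))
  for (nwk in shapes) {
    tree <- ape::read.tree(text = nwk)
    tips <- tree$tip.label
    n <- length(tips)
    sg <- stats::setNames(paste0("SG", seq_len(n)), tips)
    doms <- stats::setNames(
      rep(c("Amorphae", "Diaphoretickes"), length.out = n), paste0("SG", seq_len(n)))
    phy <- species_phylogeny(tree, sg, doms)
    for (mask in 1:(2^n - 1)) {
      present <- tips[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      presence <- stats::setNames(as.numeric(tips %in% present), tips)
      rec <- dollo_reconstruct(phy, presence)
      oracle <- bf_dollo_losses(tree, present)
      expect_equal(rec$gain_node, oracle$gain_node,
                   info = paste(nwk, mask))
      expect_equal(rec$loss_count, oracle$loss_count,
                   info = paste(nwk, mask))
    }
  }
})

test_that("flipping an absent leaf inside the gain clade never adds losses", {
  set.seed(9)
  tree <- ape::read.tree(text = balanced_newick(6))
  tips <- tree$tip.label
  phy <- species_phylogeny(
    tree, stats::setNames(paste0("SG", 1:6), tips),
    stats::setNames(rep(c("Amorphae", "Diaphoretickes"), 3), paste0("SG", 1:6)))
  for (i in 1:40) {
    presence <- stats::setNames(rbinom(6, 1, 0.5), tips)
    if (sum(presence) < 2) next
    rec <- dollo_reconstruct(phy, presence)
    clade_tips <- ape::extract.clade(tree, rec$gain_node)$tip.label
    absent_in_clade <- setdiff(clade_tips, tips[presence > 0])
    for (leaf in absent_in_clade) {
      p2 <- presence; p2[leaf] <- 1
      expect_lte(dollo_reconstruct(phy, p2)$loss_count, rec$loss_count)
    }
  }
})

test_that("LECA status needs three supergroups spanning both domains", {
  tree <- ape::read.tree(text = "(((A,B),C),((D,E),F));")
  phy <- species_phylogeny(
    tree,
    c(A = "SG1", B = "SG2", C = "SG3", D = "SG4", E = "SG5", F = "SG5"),
    c(SG1 = "Amorphae", SG2 = "Amorphae", SG3 = "Amorphae",
      SG4 = "Diaphoretickes", SG5 = "Diaphoretickes"))
  leca <- classify_leca(phy, c(A = 1, B = 1, C = 0, D = 0, E = 1, F = 0))
  expect_equal(leca$status, "LECA")        # SG1, SG2 (Amorphae) + SG5 (Diaph.)

  one_domain <- classify_leca(phy, c(A = 1, B = 1, C = 1, D = 0, E = 0, F = 0))
  expect_equal(one_domain$status, "post-LECA")   # 3 supergroups, one domain

  two_sg <- classify_leca(phy, c(A = 1, B = 0, C = 0, D = 1, E = 0, F = 0))
  expect_equal(two_sg$status, "post-LECA")       # both domains, only 2 SGs
})

test_that("the OG partition is a disjoint cover with the expected sizes", {
  phy <- toy_phylogeny()
  # A,B,C present -> 3 supergroups over both domains -> LECA;
  # A,B -> 2 supergroups -> post-LECA; single leaf -> post-LECA
  m <- rbind(OGa = c(A = 1L, B = 1L, C = 1L, D = 0L),
             OGb = c(A = 1L, B = 1L, C = 0L, D = 0L),
             OGc = c(A = 0L, B = 0L, C = 1L, D = 0L),
             OGd = c(A = 1L, B = 1L, C = 1L, D = 1L))
  part <- partition_ogs(m, phy)
  expect_setequal(part$leca, c("OGa", "OGd"))
  expect_setequal(part$post_leca, c("OGb", "OGc"))
  expect_setequal(part$all, rownames(m))
  expect_length(intersect(part$leca, part$post_leca), 0)

  # a world where every OG sits in one supergroup has no LECA OGs
  m2 <- rbind(OG1 = c(A = 1L, B = 0L, C = 0L, D = 0L),
              OG2 = c(A = 0L, B = 1L, C = 0L, D = 0L))
  expect_length(partition_ogs(m2, phy)$leca, 0)
})

test_that("classification tables round-trip through the TSV writer", {
  w <- small_world(seed = 4)
  m <- suppressMessages(subset_profile_matrix(w$observed_matrix))
  cls <- classify_ogs(m[1:20, ], w$phylogeny)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification_tsv(cls, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$og_id, cls$og_id)
  expect_equal(back$status, cls$status)
  expect_equal(back$loss_count, cls$loss_count)
})
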