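test_that("simulated phylogenies have monophyletic supergroups across domains", {
  cfg <- world_config(n_species = 8, n_supergroups = 4, n_noise_species = 0,
                      post_leca_clade_range = c(2, 4), seed = 5)
  phy <- simulate_phylogeny(cfg)
  tree <- phy$tree
  expect_equal(length(tree$tip.label), 8)
  expect_true(all(table(phy$supergroup_of) == 2))
  # each supergroup is a clade of 2 leaves
  for (sg in unique(phy$supergroup_of)) {
    leaves <- names(phy$supergroup_of)[phy$supergroup_of == sg]
    mrca <- ape::getMRCA(tree, leaves)
    expect_equal(length(ape::extract.clade(tree, mrca)$tip.label), 2)
  }
  # two domains, each held by two supergroups; the root splits them
  expect_equal(sort(as.integer(table(phy$domain_of))), c(2L, 2L))
  amorphae <- names(phy$supergroup_of)[
    phy$domain_of[phy$supergroup_of] == "Amorphae"]
  mrca_am <- ape::getMRCA(tree, amorphae)
  expect_equal(length(ape::extract.clade(tree, mrca_am)$tip.label), 4)

  phy2 <- simulate_phylogeny(cfg)
  expect_identical(ape::write.tree(phy$tree), ape::write.tree(phy2$tree))
})

test_that("Dollo evolution respects origins and the no-regain rule", {
  w <- small_world(seed = 14)
  tree <- w$phylogeny$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  for (og in rownames(w$true_matrix)) {
    origin <- w$og_origin[[og]]
    present <- colnames(w$true_matrix)[w$true_matrix[og, ] == 1L]
    clade <- if (origin == root) tree$tip.label else
      ape::extract.clade(tree, origin)$tip.label
    expect_true(all(present %in% clade))   # presence confined to origin clade
    # Dollo reconstruction places the gain inside the generating clade
    rec <- dollo_reconstruct(w$phylogeny, w$true_matrix[og, ])
    gain_tips <- if (rec$gain_node <= n_tip) tree$tip.label[rec$gain_node] else
      ape::extract.clade(tree, rec$gain_node)$tip.label
    expect_true(all(gain_tips %in% clade))
  }
})

test_that("zero loss makes ancestral OGs universal; rho = 1 clones modules", {
  w0 <- small_world(seed = 15, loss_rate = 0, fraction_post_leca = 0,
                    oversplit_fraction = 0, n_noise_species = 0)
  expect_true(all(w0$true_matrix == 1L))

  w1 <- small_world(seed = 16, rho = 1, fraction_post_leca = 0,
                    oversplit_fraction = 0, n_noise_species = 0)
  for (ogs in w1$modules) {
    if (length(ogs) < 2) next
    for (i in 2:length(ogs)) {
      expect_identical(w1$true_matrix[ogs[1], ], w1$true_matrix[ogs[i], ])
    }
  }
})

test_that("within-module profile distances widen as co-loss correlation drops", {
  mean_within <- function(rho, seed) {
    w <- small_world(seed = seed, rho = rho, fraction_post_leca = 0,
                     oversplit_fraction = 0, n_noise_species = 0)
    ds <- unlist(lapply(w$modules, function(ogs) {
      if (length(ogs) < 2) return(NULL)
      idx <- utils::combn(ogs, 2)
      vapply(seq_len(ncol(idx)), function(j) {
        cosine_distance(w$true_matrix[idx[1, j], ], w$true_matrix[idx[2, j], ])
      }, numeric(1))
    }))
    mean(ds)
  }
  expect_gt(mean_within(0, 17), mean_within(0.9, 17))
})

test_that("quality noise only flips presence to absence at the stated rate", {
  w <- small_world(seed = 18, n_noise_species = 0)
  m <- w$true_matrix
  sp <- colnames(m)[2:4]
  out <- add_quality_noise(m, sp, 0.3, seed = 2)
  obs <- out$observed_matrix
  expect_true(all(obs <= m))                       # no 0 -> 1 flips
  clean <- setdiff(colnames(m), sp)
  expect_identical(obs[, clean], m[, clean])
  expect_equal(out$noise_assignments[sp], stats::setNames(rep(0.3, 3), sp))

  # flip total within binomial 3-sigma of rate * present entries
  n_present <- sum(m[, sp])
  flips <- sum(out$n_flips)
  expect_lt(abs(flips - 0.3 * n_present), 3 * sqrt(n_present * 0.3 * 0.7) + 1)

  none <- add_quality_noise(m, sp, 0, seed = 2)
  expect_identical(none$observed_matrix, m)
  all_gone <- add_quality_noise(m, sp, 1, seed = 2)
  expect_true(all(all_gone$observed_matrix[, sp] == 0L))
})

test_that("interactome positives live inside retained modules with graded evidence", {
  w <- small_world(seed = 19)
  full <- w$interactomes$full
  g2o <- world_gene_to_og(w)
  # with full retention the positives span every module
  pos_modules <- unique(w$og_module[g2o[full$true_gene_pairs$a]])
  expect_setequal(pos_modules[!is.na(pos_modules)], names(w$modules))
  expect_setequal(full$retained_modules, names(w$modules))
  # every positive pair joins two OGs of one module
  mod_a <- w$og_module[g2o[full$true_gene_pairs$a]]
  mod_b <- w$og_module[g2o[full$true_gene_pairs$b]]
  expect_true(all(mod_a == mod_b))
  expect_true(all(g2o[full$true_gene_pairs$a] != g2o[full$true_gene_pairs$b]))

  # depleted reference keeps about half the modules
  depl <- w$interactomes$depleted
  expect_equal(length(depl$retained_modules),
               max(1, round(0.5 * length(w$modules))))

  # clean evidence model: no contamination, no noise pairs -> the filter
  # returns exactly the true positives
  w2 <- small_world(seed = 20, noise_pair_fraction = 0,
                    low_evidence_contamination = 0)
  rec <- w2$interactomes$full$records
  kept <- filter_by_evidence(rec, 5)
  expect_equal(nrow(kept), nrow(w2$interactomes$full$true_gene_pairs))
  expect_true(all(kept$n_pubs >= 5 & kept$n_pubs <= 20))

  # a reference with no module at all is rejected
  m0 <- w$true_matrix
  m0[unlist(w$modules), 3] <- 0L
  expect_error(simulate_interactome(m0, w$modules, w$og_to_genes,
                                    colnames(m0)[3], 1, w$config),
               "lacks all modules")
})

test_that("noise-free classification recovers the generating OG classes", {
  cfg <- world_config(n_noise_species = 0, seed = 31)
  w <- simulate_world(cfg)
  root <- length(w$phylogeny$tree$tip.label) + 1L
  cls <- classify_ogs(w$true_matrix, w$phylogeny)
  truth <- ifelse(w$og_origin[cls$og_id] == root, "LECA", "post-LECA")
  gen_leca <- cls$status[truth == "LECA"]
  gen_post <- cls$status[truth == "post-LECA"]
  expect_gte(mean(gen_leca == "LECA"), 0.95)
  expect_gte(mean(gen_post == "post-LECA"), 0.95)
})

test_that("world simulation is reproducible from its seed", {
  a <- small_world(seed = 22)
  b <- small_world(seed = 22)
  expect_identical(a$true_matrix, b$true_matrix)
  expect_identical(a$observed_matrix, b$observed_matrix)
  expect_identical(a$busco_absences, b$busco_absences)
  expect_identical(a$interactomes$full$records$n_pubs,
                   b$interactomes$full$records$n_pubs)
  c_ <- small_world(seed = 23)
  expect_false(identical(a$observed_matrix, c_$observed_matrix))
})
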