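test_that("quality selection sorts, breaks ties, and honours exclusions", {
  counts <- c(A = 1, B = 5, C = 3)
  expect_equal(select_by_quality(counts, 2, "least")$member_ids, c("A", "C"))
  expect_equal(select_by_quality(counts, 2, "most")$member_ids, c("B", "C"))
  expect_equal(select_by_quality(c(A = 2, B = 2, C = 9), 1, "least")$member_ids,
               "A")
  expect_equal(select_by_quality(counts, 2, "least",
                                 exclude = "A")$member_ids, c("C", "B"))
  expect_error(select_by_quality(counts, 3, "least", exclude = "A"), "exceeds")
})

test_that("greedy diversity selection follows the pair-order admission rule", {
  # hand-traceable 4-species matrix
  sp <- c("P", "Q", "R", "S")
  d <- matrix(0, 4, 4, dimnames = list(sp, sp))
  d["P", "Q"] <- d["Q", "P"] <- 0.9
  d["P", "R"] <- d["R", "P"] <- 0.8
  d["P", "S"] <- d["S", "P"] <- 0.3
  d["Q", "R"] <- d["R", "Q"] <- 0.5
  d["Q", "S"] <- d["S", "Q"] <- 0.7
  d["R", "S"] <- d["S", "R"] <- 0.6
  # diverse, threshold 0.5: seed {P,Q}; next pair P-R (0.8): R admitted
  # (d(R,P)=0.8, d(R,Q)=0.5 both >= 0.5)
  sel <- select_by_diversity(d, 3, "diverse", threshold = 0.5)
  expect_equal(sel$member_ids, c("P", "Q", "R"))
  # every within-set pair satisfies the threshold (selection invariant)
  dd <- d[sel$member_ids, sel$member_ids]
  expect_true(all(dd[upper.tri(dd)] >= 0.5))

  # threshold 0 in diverse mode admits anything: first k in pair order
  sel0 <- select_by_diversity(d, 4, "diverse", threshold = 0)
  expect_equal(length(sel0$member_ids), 4)

  # infeasible threshold: cannot grow past the seed pair
  expect_error(select_by_diversity(d, 4, "diverse", threshold = 0.85),
               "reached only")
  relaxed <- select_by_diversity(d, 4, "diverse", threshold = 0.85,
                                 auto_relax = TRUE)
  expect_equal(length(relaxed$member_ids), 4)
  expect_lt(relaxed$parameters$threshold_used, 0.85)

  # similar mode mirrors the rule with <=: seed {P,S} (0.3), then R is the
  # first candidate within 0.8 of both members
  sim <- select_by_diversity(d, 3, "similar", threshold = 0.8)
  expect_equal(sim$member_ids, c("P", "S", "R"))
  ds <- d[sim$member_ids, sim$member_ids]
  expect_true(all(ds[upper.tri(ds)] <= 0.8))
})

test_that("the diversity invariant holds on simulated species matrices", {
  w <- small_world(seed = 12)
  inp <- suppressWarnings(profiling_inputs(w))
  d <- species_distance_matrix(inp$matrix[inp$partition$leca, ])
  sel <- select_by_diversity(d, 8, "diverse", threshold = 0.05,
                             auto_relax = TRUE)
  thr <- sel$parameters$threshold_used
  dd <- d[sel$member_ids, sel$member_ids]
  expect_true(all(dd[upper.tri(dd)] >= thr))
})

test_that("random species sets are seed-reproducible and sized correctly", {
  sp <- paste0("s", 1:20)
  a <- random_species_sets(sp, k = 5, n_sets = 10, seed = 3)
  b <- random_species_sets(sp, k = 5, n_sets = 10, seed = 3)
  expect_identical(lapply(a, `[[`, "member_ids"), lapply(b, `[[`, "member_ids"))
  expect_true(all(vapply(a, function(x) length(x$member_ids), numeric(1)) == 5))
  full <- random_species_sets(sp, k = 20, n_sets = 2, seed = 1)
  expect_true(all(vapply(full, function(x) setequal(x$member_ids, sp),
                         logical(1))))
})

test_that("leave-one-out influence is complete and symmetric for twin columns", {
  w <- small_world(seed = 13)
  inp <- suppressWarnings(profiling_inputs(w))
  m <- inp$matrix[inp$partition$leca, ]
  # duplicate one column: the two copies are exchangeable, so their
  # leave-one-out deltas must coincide exactly
  m2 <- cbind(m, dupX = m[, 5])
  infl <- leave_one_out_influence(m2, inp$benchmarks$filtered)
  expect_equal(nrow(infl), ncol(m2))
  expect_identical(infl$delta_auc[infl$species == "dupX"],
                   infl$delta_auc[infl$species == colnames(m)[5]])
  # reproducible bit-for-bit
  infl2 <- leave_one_out_influence(m2, inp$benchmarks$filtered)
  expect_identical(infl, infl2)
})

test_that("top influencers split by the sign convention with lexicographic ties", {
  infl <- data.frame(species = c("A", "B", "C"),
                     delta_auc = c(-0.02, 0.01, 0))
  tops <- top_influencers(infl, 1)
  expect_equal(tops$advantageous$member_ids, "A")
  expect_equal(tops$disadvantageous$member_ids, "B")
  expect_warning(top_influencers(infl, 2), "exceeds half")
  zero <- data.frame(species = c("B", "A"), delta_auc = c(0, 0))
  expect_warning(t0 <- top_influencers(zero, 1), "zero")
  expect_equal(t0$advantageous$member_ids, "A")
})

test_that("random OG subsets honour the 63% sizing rule", {
  ogs <- paste0("OG", 1:100)
  sets <- random_og_subsets(ogs, fraction = 0.63, n_sets = 5, seed = 2)
  expect_true(all(vapply(sets, function(x) length(x$member_ids), numeric(1)) == 63))
  expect_identical(lapply(sets, `[[`, "member_ids"),
                   lapply(random_og_subsets(ogs, 0.63, 5, seed = 2),
                          `[[`, "member_ids"))
  all_of_them <- random_og_subsets(ogs, 1, 2, seed = 1)
  expect_true(all(vapply(all_of_them, function(x) setequal(x$member_ids, ogs),
                         logical(1))))
})

test_that("a genome with heavy false absences is flagged disadvantageous", {
  # one genome at 50% false-absence noise: its removal should raise the AUC
  w <- small_world(seed = 21, n_noise_species = 0)
  m_true <- suppressMessages(subset_profile_matrix(w$true_matrix))
  attr(m_true, "dropped") <- NULL
  inp <- suppressWarnings(profiling_inputs(w))
  target <- setdiff(colnames(m_true), w$reference_species)[3]
  noisy <- add_quality_noise(m_true, target, 0.5, seed = 4)$observed_matrix
  noisy <- suppressMessages(subset_profile_matrix(noisy))
  attr(noisy, "dropped") <- NULL
  infl <- leave_one_out_influence(noisy, inp$benchmarks$filtered)
  expect_gt(infl$delta_auc[infl$species == target], 0)
})

test_that("selections round-trip through JSON", {
  sel <- select_by_quality(c(A = 1, B = 5, C = 3), 2, "least")
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, path)
  back <- read_selection_json(path)
  expect_equal(back$member_ids, sel$member_ids)
  expect_equal(back$criterion, sel$criterion)
  expect_equal(back$parameters$k, sel$parameters$k)
})
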