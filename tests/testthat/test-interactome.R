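test_that("parsing collapses duplicate pairs and applies the record filters", {
  tab <- biogrid_table(
    a = c("A", "B", "A", "C", "A", "D"),
    b = c("B", "A", "B", "C", "D", "A"),
    pubmed = c("p1", "p2", "p1", "p3", "p4", "p4"),
    type = c("physical", "physical", "physical", "physical", "genetic",
             "physical"))
  rec <- parse_interaction_table(tab, organism = "9606")
  # (A,B) three times with pubmeds {p1,p2,p1} -> one record, union {p1,p2};
  # the genetic row is excluded; the self pair (C,C) is dropped and counted
  ab <- rec[rec$gene_a == "A" & rec$gene_b == "B", ]
  expect_equal(nrow(ab), 1)
  expect_setequal(ab$pubmed_ids[[1]], c("p1", "p2"))
  expect_equal(attr(rec, "n_nonphysical"), 1L)
  expect_equal(attr(rec, "n_self_dropped"), 1L)
  expect_true(all(rec$gene_a <= rec$gene_b))

  # organism filter: rows from another organism are excluded
  tab2 <- biogrid_table("X", "Y", "p9", org = "559292")
  rec2 <- parse_interaction_table(rbind(tab, tab2), organism = "9606")
  expect_false(any(rec2$gene_a == "X"))

  expect_error(parse_interaction_table(tab[, -3], organism = "9606"),
               "Pubmed")
})

test_that("a fully swap-duplicated table parses to the unduplicated records", {
  tab <- biogrid_table(c("A", "C"), c("B", "D"), c("p1", "p2"))
  dup <- rbind(tab, biogrid_table(c("B", "D"), c("A", "C"), c("p1", "p2")))
  expect_identical(parse_interaction_table(tab), parse_interaction_table(dup))
})

test_that("evidence filtering applies the five-study threshold", {
  tab <- biogrid_table(rep("A", 5), rep("B", 5), paste0("p", 1:5))
  tab <- rbind(tab, biogrid_table(rep("C", 4), rep("D", 4), paste0("q", 1:4)))
  rec <- parse_interaction_table(tab)
  kept <- filter_by_evidence(rec, 5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$gene_a, "A")           # 5 distinct PubMed ids retained
  expect_equal(nrow(filter_by_evidence(rec, 1)), nrow(rec))
  expect_error(filter_by_evidence(rec, 0), "min_pubs")
  # monotonicity: higher cut never keeps more records
  counts <- vapply(1:6, function(k) nrow(filter_by_evidence(rec, k)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("negatives are eligible pairs never reported at any evidence level", {
  rows <- rbind(
    biogrid_table(rep("A", 5), rep("B", 5), paste0("p", 1:5)),
    biogrid_table(rep("C", 5), rep("D", 5), paste0("q", 1:5)),
    biogrid_table(rep("A", 3), rep("E", 3), paste0("r", 1:3)))
  rec <- parse_interaction_table(rows)
  neg <- build_negative_set(rec, min_pubs = 5)
  # eligible = {A,B,C,D} (E never reaches 5 studies); reported pairs A-B, C-D
  # and A-E; complement within eligible:
  expect_equal(neg, data.frame(a = c("A", "A", "B", "B"),
                               b = c("C", "D", "C", "D")))
  # soundness: no negative is reported anywhere
  expect_length(intersect(pair_key <- paste(neg$a, neg$b),
                          paste(rec$gene_a, rec$gene_b)), 0)

  expect_warning(empty <- build_negative_set(rec[0, ], 5), "fewer than 2")
  expect_equal(nrow(empty), 0)

  capped <- build_negative_set(rec, 5, max_pairs = 2, seed = 7)
  expect_equal(nrow(capped), 2)
  expect_identical(capped, build_negative_set(rec, 5, max_pairs = 2, seed = 7))
})

test_that("gene pairs map to deduplicated OG pairs with drop counters", {
  g2o <- c(g1 = "OG1", g2 = "OG2", g3 = "OG1", g4 = "OG3")
  pairs <- data.frame(a = c("g1", "g1", "g2", "g9", "g3"),
                      b = c("g2", "g3", "g3", "g4", "g2"))
  out <- map_to_og_pairs(pairs, g2o)
  # (g1,g2), (g2,g3) and (g3,g2) all collapse to the same OG1-OG2 pair;
  # (g1,g3) is a same-OG self pair; (g9,g4) is unmapped
  expect_equal(out$a, "OG1")
  expect_equal(out$b, "OG2")
  expect_equal(attr(out, "n_unmapped"), 1L)
  expect_equal(attr(out, "n_self_collapsed"), 1L)
})

test_that("benchmark assembly enforces matrix coverage and disjointness", {
  m <- matrix(1L, nrow = 3, ncol = 2,
              dimnames = list(c("OG1", "OG2", "OG3"), c("s1", "s2")))
  g2o <- c(g1 = "OG1", g2 = "OG2", g3 = "OG3", g4 = "OG9")
  pos <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"))
  # every candidate negative either overlaps the positives (g1-g2) or
  # references OG9, which is not a matrix row -> assembly must refuse
  neg <- data.frame(a = c("g1", "g1", "g3"), b = c("g2", "g4", "g4"))
  expect_error(assemble_benchmark(pos, neg, g2o, m), "negative")

  neg2 <- rbind(neg, data.frame(a = "g2", b = "g3"))
  pos2 <- data.frame(a = "g1", b = "g2")
  bench2 <- assemble_benchmark(pos2, neg2, g2o, m)
  expect_equal(bench2$positives, data.frame(a = "OG1", b = "OG2"))
  expect_equal(bench2$negatives, data.frame(a = "OG2", b = "OG3"))
  expect_equal(bench2$counts$neg_overlapping_pos, 1L)
  expect_equal(bench2$counts$neg_not_in_matrix, 2L)
})

test_that("benchmarks round-trip through the TSV writer with provenance", {
  w <- small_world(seed = 5)
  bench <- suppressWarnings(profiling_inputs(w))$benchmarks$filtered
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_tsv(bench, path)
  back <- read_benchmark_tsv(path)
  expect_equal(back$positives, bench$positives)
  expect_equal(back$negatives, bench$negatives)
  expect_equal(back$provenance$min_pubs, bench$provenance$min_pubs)
})
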