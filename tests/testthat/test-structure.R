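planar_distance <- function(xy, ids) {
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(ids, ids)
  d
}

test_that("classical MDS reproduces an exact planar configuration", {
  d <- planar_distance(rbind(c(0, 0), c(3, 0), c(0, 4)), c("a", "b", "c"))
  emb <- classical_mds(d, dims = 2)
  got <- as.matrix(stats::dist(as.matrix(emb$coordinates[, -1])))
  expect_equal(sort(got[upper.tri(got)]), c(3, 4, 5), tolerance = 1e-8)
  expect_lt(emb$stress, 1e-12)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
})

test_that("identical animals embed at identical coordinates", {
  d <- matrix(c(0, 0, 0.5,
                0, 0, 0.5,
                0.5, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  emb <- classical_mds(d, dims = 2)
  xy <- as.matrix(emb$coordinates[, -1])
  rownames(xy) <- emb$coordinates$id
  expect_equal(xy["a", ], xy["b", ], tolerance = 1e-10)
  expect_error(classical_mds(d, dims = 5), "exceeds animal count")
})

test_that("axes are oriented toward the reference-A centroid", {
  set.seed(23)
  d <- random_distance_matrix(8)
  lab <- panel_labels(rownames(d)[1:3], rownames(d)[4:6], rownames(d)[7:8])
  emb <- classical_mds(d, dims = 2, labels = lab)
  xy <- as.matrix(emb$coordinates[, -1])
  expect_gte(mean(xy[1:3, 1]), 0)
  expect_gte(mean(xy[1:3, 2]), 0)
})

test_that("UPGMA handles textbook small cases", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.2)

  d3 <- matrix(c(0, 2, 6,
                 2, 0, 6,
                 6, 6, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(1, 3))
  expect_identical(upgma_merge_sets(t3), list(c("A", "B"), c("A", "B", "C")))
  expect_identical(leaf_order(t3), c("A", "B", "C"))
})

test_that("UPGMA matches a brute-force average-linkage reference on random matrices", {
  set.seed(31)
  for (rep in 1:60) {
    d <- random_distance_matrix(6)
    tree <- upgma(d)
    ref <- reference_upgma(d)
    expect_equal(tree$height, ref$heights)
    expect_identical(upgma_merge_sets(tree), ref$merges)
    expect_true(all(diff(tree$height) >= -1e-12))  # ultrametric heights
  }
})

test_that("an ultrametric input's cophenetic matrix is reproduced exactly", {
  # build an ultrametric matrix from a known tree: ((a,b):1,(c,d):2):3
  ids <- c("a", "b", "c", "d")
  d <- matrix(6, 4, 4, dimnames = list(ids, ids))
  d[1, 2] <- d[2, 1] <- 2
  d[3, 4] <- d[4, 3] <- 4
  diag(d) <- 0
  tree <- upgma(d)
  expect_equal(upgma_cophenetic(tree)[ids, ids], d)
})

test_that("leaf order is deterministic under input permutation", {
  set.seed(37)
  d <- random_distance_matrix(7)
  ord <- leaf_order(upgma(d))
  for (k in 1:5) {
    perm <- sample(rownames(d))
    expect_identical(leaf_order(upgma(d[perm, perm])), ord)
  }
  # 2-leaf tie-break: lexicographically smaller leaf goes left
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("b", "a"), c("b", "a")))
  expect_identical(leaf_order(upgma(d2)), c("a", "b"))
})

test_that("Newick export preserves topology and ultrametric depths", {
  set.seed(41)
  d <- random_distance_matrix(6)
  tree <- upgma(d)
  path <- withr::local_tempfile()
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(d))
  # leaf-to-root depth equals the root height for every tip
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths), rep(max(tree$height), 6), tolerance = 1e-9)
})

test_that("breed assignment applies the dominance-score rule", {
  ids <- c("r1", "r2", "e1", "e2")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["e1", "r1"] <- d["r1", "e1"] <- 0.2   # d_A
  d["e1", "r2"] <- d["r2", "e1"] <- 0.3   # d_B
  d["e2", "r1"] <- d["r1", "e2"] <- 0.25  # exactly equidistant
  d["e2", "r2"] <- d["r2", "e2"] <- 0.25
  d["r1", "r2"] <- d["r2", "r1"] <- 0.5
  lab <- panel_labels("r1", "r2", c("e1", "e2"))
  ba <- assign_breed(d, lab)
  expect_equal(ba$score[ba$id == "e1"], 0.2)
  expect_equal(ba$label[ba$id == "e1"], "A_DOMINANT")
  expect_equal(ba$score[ba$id == "e2"], 0)
  expect_equal(ba$label[ba$id == "e2"], "UNASSIGNED")

  # antisymmetry under swapping panel roles
  ba_swap <- assign_breed(d, panel_labels("r2", "r1", c("e1", "e2")))
  expect_equal(ba_swap$score, -ba$score)
  expect_equal(ba_swap$label[ba_swap$id == "e1"], "B_DOMINANT")

  # tie band widens the unassigned zone
  ba_band <- assign_breed(d, lab, tie_band = 0.25)
  expect_equal(ba_band$label, c("UNASSIGNED", "UNASSIGNED"))

  expect_error(assign_breed(d, panel_labels(character(0), "r2", "e1")),
               "non-empty")
  expect_error(assign_breed(d[1:3, 1:3], lab), "absent from the distance matrix")
})

test_that("reference duplicates act only through the panel mean", {
  # panel A members equidistant from each experimental animal, so
  # duplicating one changes nothing; d_B is untouched either way
  ids <- c("p1", "p2", "l1", "e1", "e2", "p1b")
  d <- matrix(0.5, 6, 6, dimnames = list(ids, ids))
  diag(d) <- 0
  for (e in c("e1", "e2")) {
    d[e, c("p1", "p2", "p1b")] <- d[c("p1", "p2", "p1b"), e] <- 0.2
  }
  d["e1", "l1"] <- d["l1", "e1"] <- 0.4
  d["e2", "l1"] <- d["l1", "e2"] <- 0.1
  base_ids <- setdiff(ids, "p1b")
  ba <- assign_breed(d[base_ids, base_ids],
                     panel_labels(c("p1", "p2"), "l1", c("e1", "e2")))
  ba_dup <- assign_breed(d, panel_labels(c("p1", "p2", "p1b"), "l1",
                                         c("e1", "e2")))
  expect_equal(ba_dup$d_A, ba$d_A)
  expect_equal(ba_dup$d_B, ba$d_B)
  expect_equal(ba_dup$score, ba$score)
  expect_equal(ba_dup$label, ba$label)
})

test_that("simulated admixed animals recover their majority ancestry", {
  cfg <- cohort_config(n_snps = 1200L, n_chrom = 3L, n_ref_a = 12L,
                       n_ref_b = 12L, missing_rate = 0, seed = 99L,
                       design = tibble::tibble(
                         alpha = c(0.8, 0.2), treatment = c("CONTROL", "CONTROL"),
                         n = c(10L, 10L)))
  set.seed(cfg$seed)
  geno <- simulate_genotypes(simulate_breed_frequencies(cfg), cfg)
  dm <- asd_matrix(geno$genotypes, partition_blocks(geno$map))
  ba <- assign_breed(dm, geno$labels)
  truth_label <- ifelse(geno$truth$alpha >= 0.5, "A_DOMINANT", "B_DOMINANT")
  expect_gte(mean(ba$label == truth_label), 0.95)
})
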