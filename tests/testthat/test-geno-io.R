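write_tsv_fixture <- function(genotype_lines, map_lines,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  gp <- file.path(dir, "geno.tsv"); mp <- file.path(dir, "map.tsv")
  writeLines(genotype_lines, gp)
  writeLines(map_lines, mp)
  c(genotype = gp, map = mp)
}

test_that("TSV genotypes round-trip through read and write", {
  p <- write_tsv_fixture(
    c("id\tm1\tm2\tm3", "a1\t0\t1\t2", "a2\t2\tNA\t0"),
    c("marker\tchrom\tpos", "m1\t1\t100", "m2\t1\t200", "m3\t1\t300")
  )
  g <- read_genotypes(p["genotype"], p["map"], dialect = "tsv")
  expect_equal(dim(g$genotypes), c(2L, 3L))
  expect_equal(nrow(g$map), 3L)
  expect_equal(unname(g$genotypes["a2", ]), c(2, NA, 0))

  dir <- withr::local_tempdir()
  out <- file.path(dir, c("g.tsv", "m.tsv"))
  write_genotypes(g$genotypes, g$map, out[1], out[2], dialect = "tsv")
  g2 <- read_genotypes(out[1], out[2], dialect = "tsv")
  expect_identical(g2$genotypes, g$genotypes)
  expect_equal(g2$map$pos, g$map$pos)
})

test_that("PLINK text dosage coding counts the lexicographically larger allele", {
  # brute force over the 3 diploid states of an A/G marker: the B allele is
  # G, so dosage must equal the number of G copies
  dir <- withr::local_tempdir()
  ped <- file.path(dir, "x.ped"); map <- file.path(dir, "x.map")
  writeLines(c("f1 a1 0 0 0 -9 A A",
               "f1 a2 0 0 0 -9 A G",
               "f1 a3 0 0 0 -9 G G",
               "f1 a4 0 0 0 -9 G A",
               "f1 a5 0 0 0 -9 0 0"), ped)
  writeLines("1 m1 0 500", map)
  g <- read_genotypes(ped, map, dialect = "plink_text")
  expect_equal(unname(g$genotypes[, "m1"]), c(0, 1, 2, 1, NA))
  expect_equal(g$map$allele_b, "G")

  # round-trip back through .ped
  out_ped <- file.path(dir, "y.ped"); out_map <- file.path(dir, "y.map")
  write_genotypes(g$genotypes, g$map, out_ped, out_map, dialect = "plink_text")
  g2 <- read_genotypes(out_ped, out_map, dialect = "plink_text")
  expect_identical(g2$genotypes, g$genotypes)
})

test_that("columns come back ordered by genome position and coding ignores row order", {
  p <- write_tsv_fixture(
    c("id\tmB\tmA", "a1\t1\t0", "a2\t2\t1"),
    c("marker\tchrom\tpos", "mB\t2\t50", "mA\t1\t900")
  )
  g <- read_genotypes(p["genotype"], p["map"], dialect = "tsv")
  expect_equal(colnames(g$genotypes), c("mA", "mB"))  # chrom 1 before chrom 2

  # permuting .ped rows permutes genotype rows but never changes the coding
  dir <- withr::local_tempdir()
  ped1 <- file.path(dir, "o1.ped"); ped2 <- file.path(dir, "o2.ped")
  mapf <- file.path(dir, "o.map")
  rows <- c("f a1 0 0 0 -9 A G C C", "f a2 0 0 0 -9 G G C T",
            "f a3 0 0 0 -9 A A T T")
  writeLines(rows, ped1)
  writeLines(rev(rows), ped2)
  writeLines(c("1 m1 0 10", "1 m2 0 20"), mapf)
  g1 <- read_genotypes(ped1, mapf, dialect = "plink_text")
  g2 <- read_genotypes(ped2, mapf, dialect = "plink_text")
  ids <- rownames(g1$genotypes)
  expect_identical(g1$genotypes, g2$genotypes[ids, ])
})

test_that("malformed genotype files fail with informative errors", {
  p <- write_tsv_fixture(
    c("id\tm1\tm2", "a1\t0\t1", "a2\t2"),
    c("marker\tchrom\tpos", "m1\t1\t100", "m2\t1\t200")
  )
  expect_error(read_genotypes(p["genotype"], p["map"], dialect = "tsv"),
               "ragged row.*line 3")

  p2 <- write_tsv_fixture(
    c("id\tm1\tm1", "a1\t0\t1"),
    c("marker\tchrom\tpos", "m1\t1\t100", "m1\t1\t200")
  )
  expect_error(read_genotypes(p2["genotype"], p2["map"], dialect = "tsv"),
               "duplicated marker")

  p3 <- write_tsv_fixture(
    c("id\tm1", "a1\t7"),
    c("marker\tchrom\tpos", "m1\t1\t100")
  )
  expect_error(read_genotypes(p3["genotype"], p3["map"], dialect = "tsv"),
               "coding error")

  dir <- withr::local_tempdir()
  ped <- file.path(dir, "bad.ped"); map <- file.path(dir, "bad.map")
  writeLines("f a1 0 0 0 -9 A ?", ped)
  writeLines("1 m1 0 100", map)
  expect_error(read_genotypes(ped, map, dialect = "plink_text"),
               "unknown allele symbol")
})

test_that("informative-SNP filter drops monomorphic, low-MAF and low-call-rate markers", {
  # 10 markers: 3 with MAF < 0.05 (monomorphic or 1 copy in 20 alleles),
  # 1 with 50% missing, 6 clean
  set.seed(7)
  g <- tiny_genotypes(cbind(
    rep(0, 10),                      # monomorphic: MAF 0
    c(1, rep(0, 9)),                 # 1/20 alleles: MAF 0.05 -> retained at 0.05
    c(rep(0, 9), 1),                 # MAF 0.05
    rep(2, 10),                      # monomorphic at dosage 2
    c(2, rep(0, 9)),                 # MAF 0.10
    matrix(rep(c(0, 1, 2, 1, 1), 10), nrow = 10)[, 1:5]
  ))
  map <- blocky_map(ncol(g))
  res <- filter_informative(g, map, maf_min = 0.05, call_rate_min = 0.9)
  expect_equal(res$report$n_low_maf, 2L)  # the two monomorphic columns
  expect_equal(res$report$n_retained, 8L)

  g2 <- g
  g2[1:5, 6] <- NA  # 50% missing
  res2 <- filter_informative(g2, map, maf_min = 0, call_rate_min = 0.9)
  expect_equal(res2$report$n_low_call_rate, 1L)
  expect_false("m06" %in% res2$map$marker)

  expect_error(filter_informative(g[, 1, drop = FALSE], map[1, ], maf_min = 0.2),
               "all .* markers removed")
})

test_that("informative-SNP filter is idempotent", {
  set.seed(11)
  g <- tiny_genotypes(matrix(sample(c(0, 1, 2, NA), 200, replace = TRUE,
                                    prob = c(0.4, 0.3, 0.25, 0.05)),
                             nrow = 10))
  map <- blocky_map(20)
  r1 <- filter_informative(g, map, maf_min = 0.05, call_rate_min = 0.8)
  r2 <- filter_informative(r1$genotypes, r1$map, maf_min = 0.05, call_rate_min = 0.8)
  expect_equal(r2$report$n_removed, 0L)
  expect_identical(r2$genotypes, r1$genotypes)
})

test_that("distance matrices survive a write/read round trip at printed precision", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- withr::local_tempfile()
  write_distance_matrix(d, path)
  expect_equal(read_distance_matrix(path), d)

  set.seed(3)
  d10 <- random_distance_matrix(10)
  write_distance_matrix(d10, path)
  back <- read_distance_matrix(path)
  expect_true(all(abs(back - d10) < 1e-12))
  expect_identical(rownames(back), rownames(d10))

  expect_error(write_distance_matrix(matrix(numeric(0), 0, 0), path), "empty")
})

test_that("panel labels validate roles and read from TSV", {
  lab <- panel_labels(c("p1", "p2"), c("l1"), c("e1", "e2"))
  expect_equal(sum(lab$role == "REF_A"), 2L)
  expect_error(panel_labels(c("p1"), c("p1"), "e1"), "more than one role")

  path <- withr::local_tempfile()
  readr::write_tsv(tibble::as_tibble(lab), path)
  lab2 <- read_panel_labels(path)
  expect_equal(lab2$id, lab$id)
  expect_equal(attr(lab2, "breed_a"), "Pietrain")
})
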