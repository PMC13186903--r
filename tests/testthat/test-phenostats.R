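test_that("exact Mann-Whitney reproduces known enumerations", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)       # 2 of choose(6,3)=20 as extreme
  expect_equal(res$mode, "exact")
  expect_equal(mann_whitney_u(c(5, 5, 7), c(5, 5, 7))$p_value, 1.0)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney equals full enumeration for all n1, n2 <= 5 with ties", {
  set.seed(53)
  for (n1 in 1:5) {
    for (n2 in 1:5) {
      x <- sample(1:4, n1, replace = TRUE)   # coarse grid forces ties
      y <- sample(1:4, n2, replace = TRUE)
      expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                   oracle_mwu_p(x, y),
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("approximate mode agrees with the tie-corrected normal approximation", {
  set.seed(59)
  x <- rnorm(30); y <- rnorm(25, 0.8)
  res <- mann_whitney_u(x, y, mode = "approximate")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  # auto switches on combined size
  expect_equal(mann_whitney_u(x, y)$mode, "approximate")
  expect_equal(mann_whitney_u(x[1:10], y[1:10])$mode, "exact")
})

test_that("Fisher exact matches known tables and exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 2 / 6)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2))$p_value, 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 1, 2), 2)), "non-negative")

  set.seed(61)
  for (rep in 1:50) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, oracle_fisher_p(tab), info = paste(tab, collapse = ","))
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Pearson correlation follows the t transform", {
  expect_equal(pearson_corr(1:10, 2 * (1:10) + 1)$estimate, 1.0)
  expect_equal(pearson_corr(1:10, -(1:10))$estimate, -1.0)
  res <- pearson_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$estimate, 0.6)
  r <- res$estimate; n <- 4
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_stat), n - 2))
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "n >= 3")
})

test_that("fibrosis heterogeneity summarises per-image spread", {
  res <- fibrosis_heterogeneity(rep(7, 10), rep(7, 10))
  expect_equal(res$difference, c(0, 0))
  expect_equal(res$sd, c(0, 0))

  res2 <- fibrosis_heterogeneity(c(2, 4, 10), c(1, 1, 1))
  la <- res2[res2$region == "LA", ]
  expect_equal(la$difference, 8)
  expect_equal(la$mean, 16 / 3)
  expect_error(fibrosis_heterogeneity(5, rep(1, 3)), "at least 2 images")
  expect_error(fibrosis_heterogeneity(c(5, 200), rep(1, 3)), "0, 100")
})

test_that("delta-delta-Ct folds are centred on controls and shift-invariant", {
  ct <- c(24, 25, 26, 23)            # targets
  ref <- c(18, 18, 18, 18)
  grp <- c("CONTROL", "CONTROL", "IHF", "IHF")
  res <- ddct_fold_change(ct, ref, grp, "CONTROL")
  expect_equal(mean(res$delta_delta_ct[grp == "CONTROL"]), 0)
  # IHF sample with delta-Ct one cycle below control mean -> fold 2
  expect_equal(res$fold_change[4], 2^(6.5 - 5))
  res_one <- ddct_fold_change(c(24, 24, 23), c(18, 18, 18),
                              c("C", "C", "I"), "C")
  expect_equal(res_one$fold_change[3], 2.0)
  # control sample at the control mean -> fold exactly 1
  expect_equal(ddct_fold_change(c(24, 24), c(18, 18), c("C", "C"), "C")$fold_change,
               c(1, 1))

  # adding a constant to every Ct of a sample (target and reference) cancels
  shift <- c(1.3, -0.7, 2.2, 0)
  res_shift <- ddct_fold_change(ct + shift, ref + shift, grp, "CONTROL")
  expect_equal(res_shift$fold_change, res$fold_change)

  expect_error(ddct_fold_change(ct, c(18, NA, 18, 18), grp, "CONTROL"),
               "reference Ct missing")
  expect_error(ddct_fold_change(ct, ref, grp, "SHAM"), "empty")
})

test_that("AF endpoints use the strict 10-second rule", {
  eps <- tibble::tibble(id = c("p1", "p1", "p2"),
                        duration_s = c(12, 4, 10))
  stim <- tibble::tibble(id = c("p1", "p2", "p3"),
                         n_stimulations = c(6L, 6L, 6L))
  res <- af_endpoints(eps, stim)
  expect_true(res$inducible[res$id == "p1"])
  expect_equal(res$fraction_inducing[res$id == "p1"], 1 / 6)
  expect_false(res$inducible[res$id == "p2"])  # 10 s is not > 10 s
  expect_false(res$inducible[res$id == "p3"])  # no episodes at all
  expect_true(all(res$fraction_inducing >= 0 & res$fraction_inducing <= 1))

  # monotone in the threshold
  res5 <- af_endpoints(eps, stim, episode_min_s = 5)
  expect_true(all(res5$n_inducing >= res$n_inducing))

  expect_error(
    af_endpoints(tibble::tibble(id = rep("p1", 7), duration_s = rep(15, 7)),
                 tibble::tibble(id = "p1", n_stimulations = 6L)),
    "more AF episodes than"
  )
})
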