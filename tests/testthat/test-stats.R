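test_that("signed-rank p-values match exact enumeration on small samples", {
  set.seed(26)
  for (n in c(8, 10, 12)) {
    x <- rnorm(n)
    y <- rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p, enum_signed_rank_p(x, y), tolerance = 1e-12)
    expect_equal(res$method, "exact")
  }
  deg <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("exact and approximate signed-rank paths agree near the cutover", {
  set.seed(27)
  diffs <- numeric(20)
  for (i in 1:20) {
    x <- rnorm(25)
    y <- rnorm(25)
    p_exact <- wilcoxon_signed_rank(x, y)$p
    d <- x - y
    p_approx <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
    diffs[i] <- abs(p_exact - p_approx)
  }
  expect_lt(max(diffs), 0.01)
})

test_that("paired t reproduces the textbook statistic and handles degeneracy", {
  set.seed(28)
  x <- rnorm(96); y <- rnorm(96)
  res <- paired_t(x, y)
  expect_equal(res$df, 95)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 95), tolerance = 1e-12)
  shift <- paired_t(x, x + 2)
  expect_true(shift$degenerate)
  expect_equal(shift$mean_diff, -2)
})

test_that("ICC consistency matches the ANOVA decomposition and printed dfs", {
  # identical days per subject, subjects differing: perfect reliability
  m1 <- matrix(rep(c(1, 5, 9, 2, 7), 4), 5, 4)
  expect_equal(icc_consistency(m1)$icc, 1)

  # a 24 x 4 design yields df1 = 23, df2 = 69
  set.seed(29)
  m <- matrix(rnorm(24 * 4, mean = 50, sd = 5), 24, 4) +
    rnorm(24, sd = 4)
  res <- icc_consistency(m)
  expect_equal(res$df1, 23)
  expect_equal(res$df2, 69)

  # random matrix agrees with the direct sums-of-squares oracle
  m10 <- matrix(rnorm(40), 10, 4)
  expect_equal(icc_consistency(m10)$icc, icc_ss_oracle(m10),
               tolerance = 1e-10)

  # consistency form: per-day additive constants change nothing
  shifted <- sweep(m10, 2, c(10, -3, 0, 7), `+`)
  expect_equal(icc_consistency(shifted)$icc, icc_consistency(m10)$icc,
               tolerance = 1e-10)

  expect_warning(icc_consistency(rbind(m10, c(NA, 1, 2, 3))))
  expect_error(icc_consistency(m10[1, , drop = FALSE]),
               class = "ps_insufficient_data")
})

test_that("Bonferroni rejects only below alpha over the family size", {
  one <- bonferroni(0.03)
  expect_equal(one$p_adjusted, 0.03)
  expect_true(one$significant)

  fam <- bonferroni(c(0.03, rep(0.5, 15)))
  expect_false(fam$significant[1])       # 0.03 not significant among 16
  expect_equal(fam$p_adjusted[1], 0.48)

  expect_equal(bonferroni(c(0, 0.2))$p_adjusted[1], 0)
  expect_true(bonferroni(c(0, 0.2))$significant[1])
})

test_that("coverage comparison tables mirror the paired layout", {
  set.seed(30)
  cov <- tidyr::expand_grid(subject = 1:10, session = 1:2,
                            task = c("RS1", "RS2"), state = 1:4)
  cov$coverage <- 25 + rnorm(nrow(cov), sd = 3) +
    ifelse(cov$state == 2 & cov$task == "RS2", 10, 0)
  tab <- compare_coverages(cov, test = "wilcoxon")
  # 6 within-task pairs per task + 4 across-task rows
  expect_equal(nrow(tab), 16)
  row_b <- tab[tab$cs_1 == 2 & tab$cs_2 == 2, ]
  expect_true(row_b$significant)
  tab_t <- compare_coverages(cov, test = "t")
  expect_equal(nrow(tab_t), 16)
  icc_tab <- reliability_icc(cov)
  expect_equal(nrow(icc_tab), 8)
  expect_equal(unique(icc_tab$df1), 9)
  expect_equal(unique(icc_tab$df2), 9)
})
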