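test_that("K-10 scoring applies the inclusive cutoff at 30", {
  expect_equal(score_k10(rep(1, 10)), list(total = 10L, group = "lower"))
  expect_equal(score_k10(rep(3, 10)), list(total = 30L, group = "higher"))
  expect_equal(score_k10(c(rep(5, 5), rep(1, 5)))$group, "higher")
  expect_equal(score_k10(rep(5, 10))$total, 50L)
  expect_equal(score_k10(rep(3, 10), cutoff = 31)$group, "lower")
  expect_error(score_k10(rep(3, 9)), "10 items")
  expect_error(score_k10(c(rep(3, 9), 6)), "1..5")
  expect_error(score_k10(c(rep(3, 9), 2.5)), "1..5")
})

test_that("two-sample tests match closed-form oracles and stats::t.test", {
  samples <- list(
    list(x = c(1, 2, 3), y = c(2, 3, 4, 5)),
    list(x = c(10, 12, 11, 14), y = c(9, 8, 10)),
    list(x = c(0.1, 0.2, 0.15, 0.3, 0.25), y = c(0.2, 0.22, 0.19, 0.21)),
    list(x = c(-1, 0, 1, 2), y = c(5, 6, 7, 8, 9)),
    list(x = c(2.5, 2.5, 3.5, 4.5), y = c(1, 1.5, 2, 2.5, 3, 3.5))
  )
  for (s in samples) {
    for (variant in c("welch", "pooled")) {
      got <- two_sample_test(s$x, s$y, variant = variant)
      ora <- if (variant == "welch") oracle_t_welch(s$x, s$y) else oracle_t_pooled(s$x, s$y)
      expect_equal(got$t, ora$t, tolerance = 1e-10)
      expect_equal(got$df, ora$df, tolerance = 1e-10)
      expect_equal(got$p, ora$p, tolerance = 1e-10)
      tt <- stats::t.test(s$x, s$y, var.equal = variant == "pooled")
      expect_equal(got$t, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(tt$parameter), tolerance = 1e-10)
      expect_equal(got$p, tt$p.value, tolerance = 1e-10)
    }
  }
  # hand-worked closed form: pooled t on {1,2,3} vs {2,3,4,5}
  got <- two_sample_test(c(1, 2, 3), c(2, 3, 4, 5), variant = "pooled")
  expect_equal(got$t, -1.5 / sqrt(1.4 * (1 / 3 + 1 / 4)), tolerance = 1e-12)
  expect_equal(got$df, 5)
})

test_that("degenerate and error cases behave as specified", {
  z <- two_sample_test(c(1, 1, 1), c(1, 1), variant = "welch")
  expect_equal(z[c("t", "p")], list(t = 0, p = 1))
  expect_error(two_sample_test(1, c(1, 2)), "at least 2")
  expect_error(two_sample_test(c(1, NA, 2), c(1, 2)), "finite")
  s <- two_sample_test_from_summaries(2, 0, 1, 2, 0, 1, variant = "welch")
  expect_equal(s$t, 0)
  expect_equal(s$df, 2)
})

test_that("swapping groups flips t and preserves p; welch df is bounded", {
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), sd = runif(1, 0.2, 3))
    a <- two_sample_test(x, y)
    b <- two_sample_test(y, x)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
    expect_lte(a$df, length(x) + length(y) - 2 + 1e-12)
  }
  # equal n and equal s: welch and pooled coincide exactly
  a <- two_sample_test_from_summaries(10, 1, 2, 10, 0.4, 2, "welch")
  b <- two_sample_test_from_summaries(10, 1, 2, 10, 0.4, 2, "pooled")
  expect_equal(a, b)
})

test_that("summary-statistic entry point reproduces cohort degrees of freedom", {
  youth <- two_sample_test_from_summaries(21, 0.134, 0.049, 31, 0.109, 0.018, "pooled")
  expect_equal(youth$df, 50)
  adult <- two_sample_test_from_summaries(94, 2.490, 0.214, 483, 2.548, 0.219, "pooled")
  expect_equal(adult$df, 575)
})

test_that("comparison table has one row per metric and respects missingness", {
  set.seed(44)
  n <- 20
  features <- data.frame(doc_id = paste0("d", 1:n))
  for (m in METRIC_ORDER) features[[m]] <- rnorm(n)
  groups <- rep(c("higher", "lower"), each = 10)

  tab <- compare_groups(features, groups)
  expect_s3_class(tab, "comparison_table")
  expect_equal(nrow(tab), 22L)
  expect_identical(tab$metric, METRIC_ORDER)
  expect_true(all(tab$p >= 0 & tab$p <= 1))

  # identical groups: t = 0, p = 1 on every row
  mirrored <- rbind(features[1:10, ], features[1:10, ])
  tab0 <- compare_groups(mirrored, groups)
  expect_true(all(tab0$t == 0))
  expect_true(all(tab0$p == 1))

  # missing values drop from that metric's row only
  features$mvr[c(1, 2, 11)] <- NA
  tab <- compare_groups(features, groups)
  row <- tab[tab$metric == "mvr", ]
  expect_equal(row$n_high, 8L)
  expect_equal(row$n_low, 9L)
  expect_equal(tab$n_high[tab$metric == "ttr"], 10L)

  # BH column appears on request and is monotone in p
  tabBH <- compare_groups(features, groups, adjust = "BH")
  expect_true(all(tabBH$p_adj >= tabBH$p - 1e-15))

  expect_error(compare_groups(features, rep("higher", n)), "at least 2")
  expect_error(compare_groups(features, groups[-1]), "align")
})

test_that("rounding interval reconciles the printed happiness row", {
  # pooled interval from the printed summaries, via the independent oracle
  ora <- oracle_t_interval(21, 0.134, 0.049, 31, 0.109, 0.018, "pooled")
  got <- t_rounding_interval(21, 0.134, 0.049, 31, 0.109, 0.018, "pooled")
  expect_equal(got, ora, tolerance = 1e-12)
  ora_w <- oracle_t_interval(21, 0.134, 0.049, 31, 0.109, 0.018, "welch")
  got_w <- t_rounding_interval(21, 0.134, 0.049, 31, 0.109, 0.018, "welch")
  expect_equal(got_w, ora_w, tolerance = 1e-12)
})
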