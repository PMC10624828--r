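test_that("mae handles exact and hand-computed cases", {
  s <- paired_series(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mae(s)$mae, 0)
  expect_equal(mae(s)$sd, 0)
  s2 <- paired_series(c(1, 2, 3), c(2, 2, 2))
  expect_equal(mae(s2)$mae, 2 / 3)
  # invariance under pair permutation
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  p <- sample(20)
  expect_equal(mae(paired_series(a, b))$mae,
               mae(paired_series(a[p], b[p]))$mae)
  expect_error(paired_series(1:3, 1:4), class = "fb_domain_error")
})

test_that("bland_altman matches hand-calculated bias and limits", {
  s <- paired_series(c(10, 20, 30), c(9, 21, 29))
  ba <- bland_altman(s)
  expect_equal(ba$bias, 1 / 3)
  expect_equal(ba$sd_diff, 2 / sqrt(3))
  expect_equal(ba$loa_low, 1 / 3 - 1.96 * 2 / sqrt(3))
  expect_equal(ba$loa_high, 1 / 3 + 1.96 * 2 / sqrt(3))
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)

  ident <- bland_altman(paired_series(c(5, 6, 7), c(5, 6, 7)))
  expect_equal(c(ident$bias, ident$loa_low, ident$loa_high), c(0, 0, 0))

  # swapping methods negates the bias and mirrors the limits
  ba_sw <- bland_altman(paired_series(c(9, 21, 29), c(10, 20, 30)))
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(ba_sw$loa_low, -ba$loa_high)
  expect_equal(ba_sw$loa_high, -ba$loa_low)
})

test_that("percentage mode divides by the pair mean", {
  # all pair means exactly 100: percentage equals absolute difference
  a <- c(101, 98, 104); b <- c(99, 102, 96)
  abs_ba <- bland_altman(paired_series(a, b), percentage = FALSE)
  pct_ba <- bland_altman(paired_series(a, b), percentage = TRUE)
  expect_equal(pct_ba$bias, abs_ba$bias)
  expect_equal(pct_ba$loa_high, abs_ba$loa_high)
  expect_error(bland_altman(paired_series(c(1, -1, 3), c(-1, 1, 3)),
                            percentage = TRUE),
               class = "fb_domain_error")
})

test_that("one-way ICC behaves at the extremes and recovers planted ratios", {
  expect_equal(icc(paired_series(c(1, 5, 9), c(1, 5, 9)))$icc, 1)
  flat <- icc(paired_series(c(3, 3, 3, 3), c(4, 4, 4, 4)))
  expect_lte(flat$icc, 0)
  degenerate <- icc(paired_series(rep(2, 5), rep(2, 5)))
  expect_true(is.na(degenerate$icc))
  expect_match(degenerate$reason, "variance")

  # Monte-Carlo: sigma_b^2 = 3, sigma_w^2 = 1 -> ICC = 0.75
  set.seed(99)
  subj <- rnorm(500, sd = sqrt(3))
  s <- paired_series(subj + rnorm(500), subj + rnorm(500))
  expect_equal(icc(s)$icc, 0.75, tolerance = 0.05 / 0.75)
  # two-way absolute-agreement variant stays close for balanced data
  expect_equal(icc(s, model = "twoway")$icc, icc(s)$icc, tolerance = 0.02)
})

test_that("paired wilcoxon matches sign-flip enumeration when exact", {
  set.seed(7)
  for (n in c(5, 8, 10, 12)) {
    a <- rnorm(n); b <- rnorm(n)
    res <- paired_wilcoxon(paired_series(a, b))
    expect_true(res$exact)
    expect_equal(res$p_value, enum_signed_rank_p(a - b), tolerance = 1e-12)
  }
  # all-positive distinct differences, n = 10: two-sided p = 2 / 2^10
  res <- paired_wilcoxon(paired_series(1:10 + (1:10) / 20, 1:10))
  expect_equal(res$p_value, 2 / 2^10)
})

test_that("paired wilcoxon handles zeros, ties and degenerate input", {
  a <- c(1, 2, 3, 4, 5, 6, 7)
  expect_error(paired_wilcoxon(paired_series(a, a + c(1, -1, 0, 0, 0, 0, 0))),
               class = "fb_domain_error")  # < 5 nonzero differences
  deg <- paired_wilcoxon(paired_series(a, a))
  expect_true(is.na(deg$p_value))
  expect_equal(deg$n_used, 0L)
  # symmetric +-1 differences: heavy ties -> approximate test, p near 1
  d <- rep(c(1, -1), 8)
  res <- paired_wilcoxon(paired_series(seq_along(d) + d, seq_along(d)))
  expect_false(res$exact)
  expect_gt(res$p_value, 0.8)
})

test_that("sensitivity/specificity come from the 2x2 table", {
  perf <- sens_spec(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)

  pred <- c(rep(TRUE, 6), rep(FALSE, 1), rep(FALSE, 12), rep(TRUE, 2))
  truth <- c(rep(TRUE, 7), rep(FALSE, 14))
  perf <- sens_spec(pred, truth)
  expect_equal(perf$sensitivity, 6 / 7)
  expect_equal(perf$specificity, 12 / 14)
  expect_equal(unname(perf$table), c(6, 2, 12, 1))

  nopos <- sens_spec(c(FALSE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(nopos$sensitivity))
  expect_match(nopos$reason, "no positives")
  expect_error(sens_spec(c(TRUE), c(TRUE, FALSE)), class = "fb_domain_error")
})

test_that("dice and iou satisfy their identities", {
  g1 <- matrix(FALSE, 20, 20); g1[1:10, 1:10] <- TRUE
  m1 <- label_mask(g1, "brain")
  expect_equal(dice_iou(m1, m1), list(dice = 1, iou = 1))
  g2 <- matrix(FALSE, 20, 20); g2[11:20, 11:20] <- TRUE
  expect_equal(dice_iou(m1, label_mask(g2, "brain")), list(dice = 0, iou = 0))
  # |A| = |B| = 100, overlap 50
  g3 <- matrix(FALSE, 20, 20); g3[6:15, 1:10] <- TRUE
  ov <- dice_iou(m1, label_mask(g3, "brain"))
  expect_equal(ov$dice, 0.5)
  expect_equal(ov$iou, 1 / 3)
  # both empty: perfect agreement by convention
  e <- label_mask(matrix(FALSE, 5, 5), "brain")
  expect_equal(dice_iou(e, e), list(dice = 1, iou = 1))
  expect_error(dice_iou(m1, e), class = "fb_domain_error")
})

test_that("bland_altman_plot returns the three-line plot", {
  set.seed(2)
  s <- paired_series(rnorm(30, 10), rnorm(30, 10))
  p <- bland_altman_plot(s, percentage = TRUE)
  expect_s3_class(p, "ggplot")
})
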