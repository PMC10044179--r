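test_that("clinical outcome definitions use the stated thresholds inclusively", {
  # recovery: caseness cut-off is >= 10, so post = 10 is not recovered
  expect_true(recovery(18, 9))
  expect_false(recovery(18, 10))
  expect_true(recovery(10, 0))

  # reliable change threshold of 6 points, inclusive both directions
  expect_equal(reliable_change(18, 12), "improved")
  expect_equal(reliable_change(18, 13), "none")
  expect_equal(reliable_change(12, 18), "deteriorated")

  # reliable recovery is the conjunction
  expect_true(reliable_recovery(18, 9))
  expect_false(reliable_recovery(13, 9))   # change 4 < 6
  expect_false(reliable_recovery(27, 12))  # post >= 10

  # percent MCID: 20% reduction, boundary inclusive
  expect_true(percent_mcid(20, 16))
  expect_false(percent_mcid(20, 17))
  expect_true(percent_mcid(10, 8))

  # absolute MCID against the band table
  tab <- data.frame(lower = c(10, 15), upper = c(14, 27), threshold = c(3, 5))
  expect_true(absolute_mcid(12, 9, tab))
  expect_false(absolute_mcid(20, 16, tab))
  zero_tab <- data.frame(lower = 0, upper = 27, threshold = 0)
  expect_true(all(absolute_mcid(c(15, 20), c(15, 12), zero_tab)))
  expect_error(absolute_mcid(9, 5, tab), "does not cover")

  expect_error(recovery(30, 5), "outside")
  expect_error(percent_mcid(0, 0), "positive")
})

test_that("improving the post-treatment score never revokes a flag", {
  set.seed(4)
  for (i in 1:50) {
    pre <- sample(10:27, 1)
    post <- sample(0:26, 1)
    better <- sample(0:post, 1)
    expect_true(recovery(pre, better) >= recovery(pre, post))
    expect_true((reliable_change(pre, better) == "improved") >=
                  (reliable_change(pre, post) == "improved"))
    expect_true(reliable_recovery(pre, better) >= reliable_recovery(pre, post))
    expect_true(percent_mcid(pre, better) >= percent_mcid(pre, post))
    expect_true(absolute_mcid(pre, better) >= absolute_mcid(pre, post))
  }
})

test_that("logistic group comparison equals the cross-product odds ratio", {
  optimal <- rep(c(TRUE, FALSE), c(60, 40))
  suboptimal <- rep(c(TRUE, FALSE), c(50, 50))
  cmp <- compare_groups_binary(optimal, suboptimal)
  oracle <- (60 * 50) / (40 * 50)
  expect_lt(abs(cmp$or - oracle) / oracle, 1e-6)
  expect_equal(cmp$or, odds_ratio_from_proportions(0.6, 0.5), tolerance = 1e-6)
  expect_true(cmp$ci_lower < cmp$or & cmp$or < cmp$ci_upper)

  equal <- compare_groups_binary(rep(c(TRUE, FALSE), 25), rep(c(TRUE, FALSE), 30))
  expect_equal(equal$or, 1, tolerance = 1e-9)

  expect_warning(zc <- compare_groups_binary(rep(TRUE, 20), rep(c(TRUE, FALSE), 10)),
                 "zero cell")
  expect_true(zc$zero_cell)
  expect_error(compare_groups_binary(rep(TRUE, 5), rep(TRUE, 5)), "non-event")
  expect_error(compare_groups_binary(logical(0), c(TRUE)), "non-empty")
})

test_that("continuous group comparison equals the mean difference and pooled-t CI", {
  a <- c(8, 10, 12); b <- c(11, 12, 13)
  cmp <- compare_groups_continuous(a, b)
  expect_equal(cmp$difference, mean(a) - mean(b), tolerance = 1e-12)
  # textbook pooled-variance two-sample oracle
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / (length(a) + length(b) - 2)
  se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  tq <- qt(0.975, df = length(a) + length(b) - 2)
  expect_equal(cmp$ci_lower, (mean(a) - mean(b)) - tq * se, tolerance = 1e-10)
  expect_equal(cmp$ci_upper, (mean(a) - mean(b)) + tq * se, tolerance = 1e-10)

  same <- compare_groups_continuous(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$difference, 0)
  expect_true(same$ci_lower < 0 && same$ci_upper > 0)

  expect_warning(tiny <- compare_groups_continuous(5, c(6, 7)), "fewer than 2")
  expect_equal(tiny$difference, -1.5)
  expect_true(is.na(tiny$ci_lower))
})

test_that("odds ratios from proportions follow the closed form", {
  expect_equal(odds_ratio_from_proportions(0.25, 0.5), (1 / 3) / 1, tolerance = 1e-12)
  expect_equal(odds_ratio_from_proportions(0.3, 0.3), 1)
  expect_error(odds_ratio_from_proportions(0, 0.5), "strictly")
  expect_error(odds_ratio_from_proportions(0.5, 1), "strictly")
})

test_that("the evaluation report compares optimal and suboptimal groups", {
  set.seed(9)
  n <- 300
  res <- data.frame(
    group = factor(rep(c("optimal", "suboptimal", "no_preference"), each = n),
                   levels = c("optimal", "suboptimal", "no_preference")),
    phq9_baseline = sample(10:27, 3 * n, TRUE)
  )
  res$phq9_post <- pmax(0, pmin(27, res$phq9_baseline -
                                  rpois(3 * n, ifelse(res$group == "optimal", 9, 7))))
  rep1 <- evaluate_allocation(res)
  expect_setequal(rep1$metrics$metric,
                  c("recovery", "reliable_change", "reliable_recovery",
                    "percent_mcid", "absolute_mcid"))
  expect_true(all(rep1$metrics$prop_optimal >= 0 & rep1$metrics$prop_optimal <= 1))
  expect_true(all(rep1$metrics$odds_ratio > 0, na.rm = TRUE))
  expect_equal(rep1$group_summary$n, c(n, n))
  md <- rep1$mean_difference
  expect_true(md$ci_lower <= md$difference && md$difference <= md$ci_upper)
  # the OR agrees with the proportions it summarises
  i <- which(rep1$metrics$metric == "recovery")
  expect_equal(rep1$metrics$odds_ratio[i],
               odds_ratio_from_proportions(rep1$metrics$prop_optimal[i],
                                           rep1$metrics$prop_suboptimal[i]),
               tolerance = 1e-6)

  expect_warning(rep2 <- evaluate_allocation(res, mcid_table = NULL), "skipped")
  expect_false("absolute_mcid" %in% rep2$metrics$metric)
})
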