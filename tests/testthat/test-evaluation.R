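# Rand index, random trees, t fit, significance

test_that("pair counts partition all unordered pairs", {
  pc <- pair_counts(c(a = 1, b = 1, c = 2), c(a = "x", c = "x", b = "y"))
  expect_equal(pc, list(TP = 0, FP = 1, FN = 1, TN = 1))
  withr::with_seed(51, {
    for (rep in 1:20) {
      n <- sample(3:30, 1)
      items <- sprintf("i%02d", seq_len(n))
      cl <- stats::setNames(sample(1:4, n, TRUE), items)
      rf <- stats::setNames(sample(letters[1:3], n, TRUE), items)
      pc <- pair_counts(cl, rf)
      expect_equal(pc$TP + pc$FP + pc$FN + pc$TN, choose(n, 2))
    }
  })
})

test_that("Rand index agrees with examples and the e1071 oracle", {
  # identical partitions -> 1
  x <- c(a = 1, b = 1, c = 2, d = 3)
  expect_equal(rand_index(x, c(a = "u", b = "u", c = "v", d = "w")), 1)
  expect_equal(rand_index(c(a = 1, b = 1, c = 2), c(a = "x", c = "x", b = "y")),
               1 / 3)
  # all singletons vs one class, N = 3 -> 0
  expect_equal(rand_index(c(a = 1, b = 2, c = 3),
                          c(a = "z", b = "z", c = "z")), 0)
  expect_error(rand_index(c(a = 1), c(b = 1)), "different item sets")
  withr::with_seed(52, {
    for (rep in 1:20) {
      n <- sample(4:40, 1)
      items <- sprintf("i%02d", seq_len(n))
      cl <- stats::setNames(sample(1:5, n, TRUE), items)
      rf <- stats::setNames(sample(letters[1:4], n, TRUE), items)
      expect_equal(rand_index(cl, rf), oracle_rand(cl, rf))
      # symmetry and invariance to label renaming
      expect_equal(rand_index(cl, rf), rand_index(rf, cl))
      renamed <- stats::setNames(match(cl, unique(cl)) + 100, items)
      expect_equal(rand_index(renamed, rf), rand_index(cl, rf))
    }
  })
})

test_that("random binary trees are valid, deterministic, and uniform over cherries", {
  expect_error(random_binary_tree("a"), "2 leaves")
  t2 <- random_binary_tree(c("a", "b"), seed = 1)
  expect_equal(t2$merge, matrix(c(-2L, -1L), 1))
  t1 <- random_binary_tree(letters[1:8], seed = 99)
  t1b <- random_binary_tree(letters[1:8], seed = 99)
  expect_identical(t1$merge, t1b$merge)
  expect_equal(t1$height, as.numeric(1:7))
  # 3 leaves: the first join picks each of the 3 pairs with probability 1/3
  counts <- withr::with_seed(53, {
    draws <- replicate(30000, {
      tr <- random_binary_tree(c("a", "b", "c"))
      paste(sort(-tr$merge[1, ]), collapse = "")
    })
    table(draws) / 30000
  })
  expect_equal(length(counts), 3L)
  expect_true(all(abs(counts - 1 / 3) < 0.01))
})

test_that("the t critical value reproduces the published-style threshold", {
  # sd -> scale conversion: sd 0.0003 with df 8.14 rounds to 0.9549
  expect_equal(round(t_critical_value(0.9544, 0.0003, 8.14, 0.05), 4),
               0.9549)
  # treating the spread as the scale parameter directly gives a larger value
  expect_gt(t_critical_value(0.9544, 0.0003, 8.14, 0.05,
                             spread_is = "scale"),
            t_critical_value(0.9544, 0.0003, 8.14, 0.05))
  expect_error(t_critical_value(0, 1, 2, 0.05), "df > 2")
})

test_that("the t fit recovers known location-scale parameters", {
  x <- withr::with_seed(54, 0.95 + 5e-4 * rt(10000, df = 8))
  fit <- protkmer:::.fit_t(x)
  expect_equal(fit$loc, 0.95, tolerance = 1e-4)
  expect_equal(fit$scale, 5e-4, tolerance = 0.2)
  expect_gt(fit$df, 4); expect_lt(fit$df, 16)  # df MLE is noisy
})

test_that("degenerate references give degenerate but valid nulls", {
  # every item its own class: the DP splits everything, all pairs TN
  items <- sprintf("i%d", 1:8)
  ref_single <- stats::setNames(items, items)
  null1 <- null_rand_distribution(ref_single, n_trees = 100, seed = 3)
  expect_true(all(null1$samples == 1))
  expect_true(is.na(null1$fitted_df))
  # one class for everything: root merge always optimal
  ref_one <- stats::setNames(rep("c", 8), items)
  null2 <- null_rand_distribution(ref_one, n_trees = 100, seed = 3)
  expect_true(all(null2$samples == 1))
  expect_error(null_rand_distribution(c(a = "x"), 100), "2 items")
  expect_error(null_rand_distribution(ref_one, 10), "at least 100")
})

test_that("null means are reproducible across seeds", {
  items <- sprintf("i%02d", 1:20)
  ref <- stats::setNames(rep(letters[1:5], each = 4), items)
  n1 <- null_rand_distribution(ref, n_trees = 2000, seed = 1)
  n2 <- null_rand_distribution(ref, n_trees = 2000, seed = 2)
  expect_true(all(n1$samples >= 0 & n1$samples <= 1))
  expect_lt(abs(n1$mean - n2$mean), 0.005)
  # same seed reproduces exactly
  n1b <- null_rand_distribution(ref, n_trees = 2000, seed = 1)
  expect_identical(n1$samples, n1b$samples)
})

test_that("significance is right-sided and strict at the boundary", {
  items <- sprintf("i%02d", 1:20)
  ref <- stats::setNames(rep(letters[1:4], each = 5), items)
  null <- null_rand_distribution(ref, n_trees = 500, seed = 9)
  at_boundary <- significance_test(null$critical_value, null)
  expect_false(at_boundary$significant)
  top <- significance_test(1.0, null)
  expect_true(top$significant)
  expect_lte(top$p_fitted, 0.05)
  expect_gte(top$p_empirical, 0)
})
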