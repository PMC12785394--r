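# Distance functions and distance matrices

test_that("the general distance specializes to L1 and L2", {
  p <- c(1, 0, 0, 0); q <- c(0, 1, 0, 0)
  expect_equal(minkowski_distance(p, p, 1, 1), 0)
  expect_equal(minkowski_distance(p, p, 2, 2), 0)
  expect_equal(minkowski_distance(p, q, 1, 1), 2)
  expect_equal(minkowski_distance(c(1, 0), c(0, 1), 2, 2), sqrt(2))
  withr::with_seed(5, {
    x <- rand_prob_vec(50); y <- rand_prob_vec(50)
    expect_equal(minkowski_distance(x, y, 1, 1), sum(abs(x - y)))
    expect_equal(minkowski_distance(x, y, 2, 2), sqrt(sum((x - y)^2)))
    # a and b act independently
    expect_equal(minkowski_distance(x, y, 3, 2), sum((x - y)^2)^(1 / 3))
  })
  expect_error(minkowski_distance(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("correlation distance maps Pearson r from [-1,1] to [0,1]", {
  expect_equal(correlation_distance(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(correlation_distance(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)), 1)
  # r = -1/3 for disjoint unit masses in dimension 4
  expect_equal(correlation_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), 2 / 3)
  expect_error(correlation_distance(c(0.25, 0.25, 0.25, 0.25), c(1, 0, 0, 0)),
               "constant")
})

test_that("top-k-mer sets have exact size with index tie-breaks", {
  v <- c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0)
  expect_identical(as.integer(top_kmer_set(v, 0.1)), 8L)
  # all equal: ties broken by ascending index
  expect_identical(as.integer(top_kmer_set(rep(0.1, 10), 0.3)), 1:3)
  # size is round(a * n), half rounded up
  expect_equal(attr(top_kmer_set(rand_prob_vec(10), 0.25), "s"), 3L)
  expect_equal(attr(top_kmer_set(rand_prob_vec(8000), 0.1), "s"), 800L)
  expect_equal(attr(top_kmer_set(rand_prob_vec(8000), 0.05), "s"), 400L)
  expect_error(top_kmer_set(rand_prob_vec(10), 0.01), "zero")
})

test_that("intersection distance measures top-set overlap", {
  withr::with_seed(6, {
    p <- rand_prob_vec(40)
    expect_equal(intersection_distance(p, p, 0.1), 0)
  })
  # disjoint top sets -> 1
  p <- c(5, 4, 3, 2, 1, rep(0, 5)) / 15
  q <- c(rep(0, 5), 1, 2, 3, 4, 5) / 15
  expect_equal(intersection_distance(p, q, 0.5), 1)
  # top-5 sets sharing 3 members -> 1 - 3/5
  r <- c(5, 4, 3, 0, 0, 0, 0, 0, 2, 1) / 15
  expect_equal(intersection_distance(p, r, 0.5), 0.4)
})

test_that("metric properties hold on random probability vectors", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      x <- rand_prob_vec(12); y <- rand_prob_vec(12); z <- rand_prob_vec(12)
      for (ab in list(c(1, 1), c(2, 2))) {
        dxy <- minkowski_distance(x, y, ab[1], ab[2])
        dyx <- minkowski_distance(y, x, ab[1], ab[2])
        expect_identical(dxy, dyx)
        expect_lte(dxy, minkowski_distance(x, z, ab[1], ab[2]) +
                        minkowski_distance(z, y, ab[1], ab[2]) + 1e-12)
      }
      expect_lte(minkowski_distance(x, y, 1, 1), 2)
      dc <- correlation_distance(x, y)
      expect_gte(dc, 0); expect_lte(dc, 1)
      di <- intersection_distance(x, y, 0.25)
      expect_gte(di, 0); expect_lte(di, 1)
      expect_identical(di, intersection_distance(y, x, 0.25))
    }
  })
})

test_that("distance matrices match direct pairwise calls and stats::dist", {
  withr::with_seed(8, {
    vecs <- lapply(1:4, function(i) rand_prob_vec(30))
    names(vecs) <- c("w", "x", "y", "z")
    for (metric in c("l1", "l2", "corr")) {
      d <- kmer_distance_matrix(vecs, metric = metric)
      expect_true(isSymmetric(unname(d)))
      expect_equal(unname(diag(d)), rep(0, 4))
      f <- switch(metric,
                  l1 = function(p, q) minkowski_distance(p, q, 1, 1),
                  l2 = function(p, q) minkowski_distance(p, q, 2, 2),
                  corr = correlation_distance)
      for (i in 1:3) for (j in (i + 1):4)
        expect_equal(d[i, j], f(vecs[[i]], vecs[[j]]))
    }
    # cross-check L1/L2 against stats::dist
    X <- do.call(rbind, vecs)
    expect_equal(unname(kmer_distance_matrix(vecs, "l1")),
                 unname(as.matrix(dist(X, "manhattan"))),
                 ignore_attr = TRUE)
    expect_equal(unname(kmer_distance_matrix(vecs, "l2")),
                 unname(as.matrix(dist(X, "euclidean"))),
                 ignore_attr = TRUE)
    # identical vectors -> zero matrix
    d0 <- kmer_distance_matrix(list(a = vecs[[1]], b = vecs[[1]]), "l1")
    expect_true(all(d0 == 0))
    # errors name the offending pair
    expect_error(
      kmer_distance_matrix(list(a = c(0.5, 0.5), b = c(1, 0, 0)), "l1"),
      "dimension")
  })
})

test_that("distance matrices round-trip through JSON", {
  withr::with_seed(9, {
    vecs <- list(a = rand_prob_vec(20), b = rand_prob_vec(20),
                 c = rand_prob_vec(20))
    d <- kmer_distance_matrix(vecs, metric = "l2")
    path <- withr::local_tempfile(fileext = ".json")
    write_distance_matrix_json(d, path)
    d2 <- read_distance_matrix_json(path)
    expect_equal(d2, d, tolerance = 1e-12)
    expect_identical(attr(d2, "metric"), "l2")
  })
})
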