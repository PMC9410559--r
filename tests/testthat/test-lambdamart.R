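test_that("lambda gradients match hand evaluation", {
  # all labels equal -> zero gradients
  z <- compute_lambdas(c(0.3, 0.1), c(1, 1), k = 2)
  expect_identical(z$lambda, c(0, 0))
  expect_identical(z$hessian, c(0, 0))
  # two candidates, equal scores: |dNDCG@2| = 1 - 1/log2(3), rho = 1/2
  lh <- compute_lambdas(c(0, 0), c(1L, 0L), k = 2, sigma = 1)
  expected <- 0.5 * (1 - 1 / log2(3))
  expect_equal(lh$lambda, c(expected, -expected), tolerance = 1e-10)
  expect_equal(expected, 0.18454, tolerance = 1e-4)
  expect_equal(lh$hessian, rep(0.25 * (1 - 1 / log2(3)), 2))
  # widely separated pair saturates
  sat <- compute_lambdas(c(10, 0), c(1L, 0L), k = 2)
  expect_lt(abs(sat$lambda[[1]]), 1e-4)
})

test_that("lambdas sum to zero and hessians are non-negative per group", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    lh <- compute_lambdas(rnorm(n), rbinom(n, 1, 0.4), k = sample(1:10, 1))
    expect_equal(sum(lh$lambda), 0, tolerance = 1e-12)
    expect_true(all(lh$hessian >= 0))
  }
})

test_that("regression trees split greedily and respect the leaf cap", {
  x <- matrix(c(0.1, 0.2, 0.8, 0.9,
                0.5, 0.5, 0.5, 0.5), 4, 2)
  # constant targets -> single leaf with the Newton value
  t0 <- fit_tree(x, rep(2, 4), rep(1, 4), n_leaves = 4)
  expect_identical(nrow(t0), 1L)
  expect_equal(t0$value, 8 / (4 + 1e-9))
  # targets split perfectly by feature 1
  t1 <- fit_tree(x, c(-1, -1, 1, 1), rep(0.5, 4), n_leaves = 2)
  expect_identical(sum(t1$feature != 0L), 1L)
  expect_identical(t1$feature[[1]], 1L)
  set.seed(3)
  t2 <- fit_tree(matrix(runif(400), 100, 4), rnorm(100), runif(100),
                 n_leaves = 2)
  expect_lte(sum(t2$feature == 0L), 2L)
})

test_that("training converges on a separable listwise fixture", {
  g <- separable_groups(seed = 2)
  cfg <- ranker_config(n_trees = 20, truncation_k = 5, shrinkage = 0.2,
                       n_leaves = 3)
  model <- lambdamart(g$x, g$y, g$group, cfg)
  expect_equal(mean_train_ndcg(model, g$x, g$y, g$group, 5), 1.0)
  # every positive outranks every negative after training
  s <- predict(model, g$x)
  for (ix in split(seq_along(g$y), g$group))
    expect_gt(min(s[ix][g$y[ix] == 1]), max(s[ix][g$y[ix] == 0]))
})

test_that("a zero-tree model scores constantly and ranks by input order", {
  g <- separable_groups(n_groups = 2, seed = 4)
  m0 <- lambdamart(g$x, g$y, g$group, ranker_config(n_trees = 0))
  s <- predict(m0, g$x)
  expect_identical(length(unique(s)), 1L)
  ranked <- predict(m0, g$x, group = g$group,
                    candidates = paste0("d", sequence(rle(g$group)$lengths)))
  expect_identical(ranked$q1$disease, paste0("d", 1:10))
  expect_identical(ranked$q1$rank, 1:10)
  expect_identical(feature_usage(m0), c(cf = 0L, lr = 0L, rf = 0L, svm = 0L))
})

test_that("boosting never degrades mean training NDCG@k", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    x <- matrix(runif(4 * n), n, 4,
                dimnames = list(NULL, c("cf", "lr", "rf", "svm")))
    y <- rbinom(n, 1, 0.3)
    grp <- rep(paste0("q", 1:4), each = 10)
    if (!any(vapply(split(y, grp), function(v) any(v == 1) && any(v == 0),
                    logical(1)))) next
    cfg <- ranker_config(n_trees = 15, truncation_k = 5, shrinkage = 0.1,
                         n_leaves = 4)
    m <- lambdamart(x, y, grp, cfg)
    m0 <- lambdamart(x, y, grp, ranker_config(n_trees = 0))
    expect_gte(mean_train_ndcg(m, x, y, grp), mean_train_ndcg(m0, x, y, grp))
  }
})

test_that("training errors without a trainable group and ranks are permutations", {
  x <- matrix(runif(12), 6, 2)
  expect_error(lambdamart(x, rep(1L, 6), rep("q", 6), ranker_config()),
               "trainable")
  g <- separable_groups(n_groups = 3, seed = 9)
  m <- lambdamart(g$x, g$y, g$group, ranker_config(n_trees = 5,
                                                   shrinkage = 0.2))
  ranked <- predict(m, g$x, group = g$group)
  for (r in ranked) {
    expect_setequal(r$rank, seq_len(nrow(r)))
    expect_true(all(diff(r$score) <= 0))
  }
})

test_that("feature usage counts internal splits and conserves the total", {
  g <- separable_groups(seed = 6)
  m <- lambdamart(g$x, g$y, g$group,
                  ranker_config(n_trees = 10, n_leaves = 4, shrinkage = 0.2))
  u <- feature_usage(m)
  total_splits <- sum(vapply(m$trees, function(tr) sum(tr$feature != 0L),
                             integer(1)))
  expect_identical(sum(u), total_splits)
  expect_named(u, c("cf", "lr", "rf", "svm"))
  one <- fit_tree(matrix(c(0, 1, 0.5, 0.5, 0.5, 0.5), 2, 3),
                  c(-1, 1), c(1, 1), 2)
  m1 <- structure(list(base_score = 0, trees = list(one), shrinkage = 1,
                       feature_names = c("a", "b", "c"),
                       config = ranker_config(n_trees = 1)),
                  class = "lambdamart")
  expect_identical(feature_usage(m1), c(a = 1L, b = 0L, c = 0L))
})

test_that("model training and persistence are bit-reproducible", {
  g <- separable_groups(seed = 8)
  cfg <- ranker_config(n_trees = 8, shrinkage = 0.2, seed = 5)
  m1 <- lambdamart(g$x, g$y, g$group, cfg)
  m2 <- lambdamart(g$x, g$y, g$group, cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_lambdamart(m1, f1); write_lambdamart(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_lambdamart(f1)
  expect_identical(predict(back, g$x), predict(m1, g$x))
  expect_identical(back$config$truncation_k, cfg$truncation_k)
  expect_identical(feature_usage(back), feature_usage(m1))
})
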