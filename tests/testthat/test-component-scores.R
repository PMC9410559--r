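make_small_ref <- function() {
  sp <- matrix(c(1, 0.5, 0.2,
                 0.5, 1, 0.3,
                 0.2, 0.3, 1), 3, byrow = TRUE,
               dimnames = list(paste0("p", 1:3), paste0("p", 1:3)))
  sd <- matrix(c(1, 0.4, 0.4, 1), 2,
               dimnames = list(c("d1", "d2"), c("d1", "d2")))
  lab <- rbind(p1 = c(1L, 0L), p2 = c(0L, 1L), p3 = c(0L, 0L))
  colnames(lab) <- c("d1", "d2")
  list(sp = sp, sd = sd, lab = lab)
}

test_that("pair features concatenate similarity rows with the right label", {
  r <- make_small_ref()
  pairs <- rbind(c("p1", "d1"), c("p2", "d2"), c("p3", "d1"))
  f <- build_pair_features(r$sp, r$sd, pairs, r$lab)
  expect_identical(ncol(f$x), 5L)            # 3 reference piRNAs + 2 diseases
  expect_identical(f$label, c(1L, 1L, 0L))
  expect_equal(unname(f$x[1, ]), c(1, 0.5, 0.2, 1, 0.4))
  # a query identical to reference j carries 1.0 at position j
  expect_equal(unname(f$x[2, 2]), 1)
  expect_error(build_pair_features(r$sp[1:2, ], r$sd,
                                   rbind(c("p3", "d1")), r$lab),
               "p3")
})

test_that("collaborative filtering is a neighbourhood label average", {
  r <- make_small_ref()
  # query q similar only to p1 -> inherits p1's labels exactly
  sp_q <- matrix(c(1, 0, 0, 1, 0.5, 0), 2, 3, byrow = TRUE,
                 dimnames = list(c("qa", "qb"), paste0("p", 1:3)))
  got <- cf_scores(r$lab, sp_q, rbind(c("qa", "d1"), c("qa", "d2")))
  expect_equal(got, c(1, 0))
  # two neighbours, sims 1.0 / 0.5, labels for d2 are 0 / 1 -> 1/3
  expect_equal(cf_scores(r$lab, sp_q, rbind(c("qb", "d2"))), 1 / 3)
  # all-zero similarity -> 0 by convention
  sp_0 <- matrix(0, 1, 3, dimnames = list("qz", paste0("p", 1:3)))
  expect_equal(cf_scores(r$lab, sp_0, rbind(c("qz", "d1"))), 0)
})

test_that("a benchmark pair's own label never leaks into its CF score", {
  set.seed(8)
  n <- 12
  sp <- matrix(runif(n * n, 0.2, 0.9), n)
  sp <- (sp + t(sp)) / 2; diag(sp) <- 1
  dimnames(sp) <- list(paste0("p", 1:n), paste0("p", 1:n))
  lab <- matrix(rbinom(n * 3, 1, 0.4), n,
                dimnames = list(paste0("p", 1:n), paste0("d", 1:3)))
  pair <- rbind(c("p4", "d2"))
  v1 <- cf_scores(lab, sp, pair)
  lab2 <- lab; lab2["p4", "d2"] <- 1L - lab2["p4", "d2"]
  expect_identical(v1, cf_scores(lab2, sp, pair))
})

test_that("the neighbourhood bound restricts CF to the closest references", {
  lab <- matrix(c(1L, 1L, 0L), 3, 1,
                dimnames = list(paste0("p", 1:3), "d1"))
  sp_q <- matrix(c(0.9, 0.8, 0.1), 1, 3,
                 dimnames = list("q", paste0("p", 1:3)))
  # k = 2 keeps p1, p2 (both label 1) and drops p3 (label 0)
  expect_equal(cf_scores(lab, sp_q, rbind(c("q", "d1")), k_neighbors = 2), 1)
  # unbounded: (0.9 + 0.8) / 1.8
  expect_equal(cf_scores(lab, sp_q, rbind(c("q", "d1")), k_neighbors = Inf),
               1.7 / 1.8)
})

test_that("the three classifiers separate a separable toy set", {
  f <- separable_features(seed = 3)
  sc <- train_classifiers(f, classifier_config(seed = 3))
  for (name in c("lr", "rf", "svm")) {
    p <- sc[[name]](f$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(min(p[f$label == 1]), max(p[f$label == 0]))
  }
  expect_error(train_classifiers(list(x = f$x, label = rep(1L, nrow(f$x))),
                                 classifier_config()),
               "single class")
})

test_that("classifier training is deterministic given config and seed", {
  f <- separable_features(seed = 5)
  set.seed(99); probe <- matrix(runif(20 * ncol(f$x)), 20)
  colnames(probe) <- colnames(f$x)
  p1 <- sapply(train_classifiers(f, classifier_config(seed = 7))[1:3],
               function(s) s(probe))
  p2 <- sapply(train_classifiers(f, classifier_config(seed = 7))[1:3],
               function(s) s(probe))
  expect_identical(p1, p2)
})

test_that("score stacking keeps the fixed (CF, LR, RF, SVM) order and range", {
  f <- separable_features(seed = 11)
  sc <- train_classifiers(f, classifier_config(seed = 11))
  cf <- ifelse(f$label == 1, runif(nrow(f$x), 0.6, 1),
               runif(nrow(f$x), 0, 0.4))
  q <- score_pairs(sc, cf, f)
  expect_identical(colnames(q), c("cf", "lr", "rf", "svm"))
  expect_equal(unname(q[, "cf"]), cf)
  expect_true(all(q >= 0 & q <= 1))
  # positives dominate coordinate-wise in the mean
  expect_true(all(colMeans(q[f$label == 1, ]) > colMeans(q[f$label == 0, ])))
  expect_error(score_pairs(sc, cf[-1], f), "different pair sets")
})
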