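test_that("degenerate labels give constant trees", {
  X <- matrix(rnorm(40), 20, 2)
  m <- train_random_forest(X, rep(1L, 20), n_trees = 5, seed = 1)
  for (tr in m$trees) expect_true(all(tr$leaf_value == 1))
  expect_equal(predict_proba(m, X), rep(1, 20))
  expect_equal(m$base_value, 1)
})

test_that("separable one-dimensional data is fit exactly", {
  x <- matrix(c(seq(-1, -0.1, length.out = 10), seq(0.1, 1, length.out = 10)))
  y <- rep(c(0L, 1L), each = 10)
  m <- train_random_forest(x, y, n_trees = 20, seed = 2)
  expect_equal(as.numeric(predict_proba(m, x) > 0.5), y, ignore_attr = TRUE)
})

test_that("training is bit-deterministic under a fixed seed", {
  d <- random_binary_data(50, 4, seed = 3)
  m1 <- train_random_forest(d$X, d$y, n_trees = 7, seed = 11)
  m2 <- train_random_forest(d$X, d$y, n_trees = 7, seed = 11)
  expect_identical(m1, m2)
  m3 <- train_random_forest(d$X, d$y, n_trees = 7, seed = 12)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("trained trees conserve cover and respect structural invariants", {
  d <- random_binary_data(80, 5, seed = 4)
  m <- train_random_forest(d$X, d$y, n_trees = 10, max_depth = 6, seed = 5)
  expect_invisible(validate_ensemble(m))
  for (tr in m$trees) {
    internal <- which(tr$children_left >= 0L)
    for (i in internal) {
      expect_identical(tr$node_cover[tr$children_left[i] + 1L] +
                         tr$node_cover[tr$children_right[i] + 1L],
                       tr$node_cover[i])
    }
    expect_true(all(tr$leaf_value >= 0 & tr$leaf_value <= 1))
  }
})

test_that("ensemble probability is the mean of per-tree outputs and bounded by them", {
  d <- random_binary_data(60, 4, seed = 6)
  m <- train_random_forest(d$X, d$y, n_trees = 9, max_depth = 4, seed = 7)
  Xnew <- matrix(rnorm(30 * 4), 30, 4)
  per_tree_oracle <- sapply(m$trees, function(tr)
    apply(Xnew, 1L, route_tree_value, tree = tr))
  expect_equal(predict_proba(m, Xnew), rowMeans(per_tree_oracle), tolerance = 1e-12)
  expect_equal(predict_proba(m, Xnew, per_tree = TRUE), per_tree_oracle,
               ignore_attr = TRUE)
  p <- predict_proba(m, Xnew)
  expect_true(all(p >= apply(per_tree_oracle, 1, min) - 1e-12))
  expect_true(all(p <= apply(per_tree_oracle, 1, max) + 1e-12))
})

test_that("weighted bootstrap balances the classes it is told to", {
  # one positive in forty: unweighted trees almost never see it; weighted do
  explspace:::with_preserved_seed(8, {
    X <- matrix(rnorm(80), 40, 2)
    X[1, ] <- c(5, 5)
  })
  y <- c(1L, rep(0L, 39))
  w <- inverse_frequency_weights(y)
  mw <- train_random_forest(X, y, n_trees = 50, sample_weights = w, seed = 9)
  m0 <- train_random_forest(X, y, n_trees = 50, seed = 9)
  expect_gt(predict_proba(mw, X[1, , drop = FALSE]),
            predict_proba(m0, X[1, , drop = FALSE]))
  expect_gt(predict_proba(mw, X[1, , drop = FALSE]), 0.5)
})

test_that("input contracts are enforced", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_random_forest(X, rep(2L, 10)), "binary")
  expect_error(train_random_forest(X, rep(0:1, 5), n_trees = 0), "n_trees")
  expect_error(train_random_forest(X, rep(0:1, 5), mtry = 3), "mtry")
  m <- train_random_forest(X, rep(0:1, 5), n_trees = 2, seed = 1)
  expect_error(predict_proba(m, matrix(0, 2, 3)), "columns")
})

test_that("serialization round-trips losslessly", {
  # single-leaf tree
  m1 <- train_random_forest(matrix(rnorm(10)), rep(1L, 10), n_trees = 1, seed = 1)
  expect_identical(deserialize_ensemble(serialize_ensemble(m1))$trees, m1$trees)
  # trained 10-tree forest: identical arrays and identical predictions
  d <- random_binary_data(70, 5, seed = 10)
  m <- train_random_forest(d$X, d$y, n_trees = 10, seed = 11)
  back <- deserialize_ensemble(serialize_ensemble(m))
  expect_identical(back$trees, m$trees)
  Xnew <- matrix(rnorm(100 * 5), 100, 5)
  expect_identical(predict_proba(back, Xnew), predict_proba(m, Xnew))
})

test_that("malformed documents are rejected with the offending node named", {
  d <- random_binary_data(40, 3, seed = 12)
  m <- train_random_forest(d$X, d$y, n_trees = 1, max_depth = 2, seed = 13)
  bad <- m
  bad$trees[[1]]$node_cover[2] <- bad$trees[[1]]$node_cover[2] + 5
  expect_error(deserialize_ensemble(serialize_ensemble(bad)),
               "node 0.*covers")
  bad2 <- m
  bad2$trees[[1]]$leaf_value[1] <- 1.5
  expect_error(validate_ensemble(bad2), "node 0.*leaf_value")
})

test_that("the binary superset task on default synthetic data is learned well", {
  ds <- generate_hypercube_dataset(synthetic_spec(seed = 0))
  yb <- split_supersets(ds$y_subclass, 0:2)
  held <- explspace:::with_preserved_seed(99, sample(nrow(ds$X), 320))
  m <- train_random_forest(ds$X[-held, ], yb[-held], seed = 100)
  acc <- mean((predict_proba(m, ds$X[held, ]) > 0.5) == yb[held])
  expect_gt(acc, 0.9)
})
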