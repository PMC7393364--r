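test_that("conditional tree expectations match direct evaluation and hand values", {
  st <- stump_ensemble()$trees[[1]]
  # fully conditioned: the routed leaf; unconditioned: cover-weighted mean
  expect_equal(tree_expected_value(st, x = 1, known = 1L), 0.8)
  expect_equal(tree_expected_value(st, x = -1, known = 1L), 0.2)
  expect_equal(tree_expected_value(st, x = 1, known = integer(0)), 0.5)
})

test_that("tree expectations agree with leaf enumeration on deeper trees", {
  for (seed in 1:5) {
    d <- random_binary_data(60, 4, seed = seed)
    m <- train_random_forest(d$X, d$y, n_trees = 1, max_depth = 3, seed = seed)
    tr <- m$trees[[1]]
    x <- d$X[seed, ]
    for (known in list(integer(0), 1L, c(1L, 3L), 1:4)) {
      expect_equal(tree_expected_value(tr, x, known),
                   leaf_enum_expected_value(tr, x, known), tolerance = 1e-12)
    }
  }
})

test_that("brute-force Shapley satisfies the closed-form, symmetry and efficiency axioms", {
  m <- stump_ensemble()
  # one player takes the whole surplus
  expect_equal(brute_force_shap(m, x = 1), 0.3)
  expect_equal(brute_force_shap(m, x = -1), -0.3)

  # symmetric two-feature tree: x2 <= 0 and x1 <= 0 lead to the same leaves
  sym <- structure(list(trees = list(list(
    children_left  = c(1L, 3L, 5L, -1L, -1L, -1L, -1L),
    children_right = c(2L, 4L, 6L, -1L, -1L, -1L, -1L),
    split_feature  = c(0L, 1L, 1L, -1L, -1L, -1L, -1L),
    split_threshold = c(0, 0, 0, NA, NA, NA, NA),
    leaf_value = c(0.45, 0.3, 0.6, 0.1, 0.5, 0.5, 0.7),
    node_cover = c(100, 50, 50, 25, 25, 25, 25))),
    n_features = 2L, base_value = 0.45, n_trees = 1L, feature_names = NULL),
    class = "tree_ensemble")
  phi <- brute_force_shap(sym, c(-1, -1))
  expect_equal(phi[1], phi[2], tolerance = 1e-12)

  # efficiency on a trained forest
  d <- random_binary_data(50, 5, seed = 20)
  m2 <- train_random_forest(d$X, d$y, n_trees = 6, max_depth = 3, seed = 21)
  for (i in c(1, 25)) {
    phi <- brute_force_shap(m2, d$X[i, ])
    expect_equal(m2$base_value + sum(phi),
                 unname(predict_proba(m2, d$X[i, , drop = FALSE])),
                 tolerance = 1e-10)
  }
  expect_error(brute_force_shap(
    train_random_forest(matrix(rnorm(20 * 13), 20, 13), rep(0:1, 10),
                        n_trees = 1, seed = 1),
    rnorm(13)), "allow_large")
})

test_that("tree_shap equals the brute-force oracle on random small forests", {
  worst <- 0
  for (seed in 1:8) {
    p <- 2L + (seed %% 5L)
    d <- random_binary_data(60, p, seed = 30 + seed)
    m <- train_random_forest(d$X, d$y, n_trees = 1L + (seed %% 6L),
                             max_depth = 4, seed = 40 + seed)
    for (i in c(3L, 37L)) {
      worst <- max(worst, max(abs(tree_shap(m, d$X[i, ]) -
                                    brute_force_shap(m, d$X[i, ]))))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("a feature unused by every tree gets exactly zero attribution", {
  d <- random_binary_data(60, 2, seed = 50)
  X <- cbind(d$X, dummy = rnorm(60))
  # force splits away from the dummy column by making it constant in training
  X[, 3] <- 0
  m <- train_random_forest(X, d$y, n_trees = 5, seed = 51)
  expect_true(all(vapply(m$trees, function(tr) all(tr$split_feature != 2L),
                         logical(1))))
  x <- c(d$X[1, ], 7)  # arbitrary dummy value at explanation time
  expect_identical(tree_shap(m, x)[3], 0)
})

test_that("ensemble attributions average per-tree attributions", {
  d <- random_binary_data(50, 4, seed = 60)
  m2 <- train_random_forest(d$X, d$y, n_trees = 2, max_depth = 3, seed = 61)
  singles <- lapply(1:2, function(t) {
    m1 <- m2
    m1$trees <- m2$trees[t]
    m1$n_trees <- 1L
    tree_shap(m1, d$X[5, ])
  })
  expect_equal(tree_shap(m2, d$X[5, ]), (singles[[1]] + singles[[2]]) / 2,
               tolerance = 1e-12)
})

test_that("explain_matrix holds local accuracy and flags constant models", {
  d <- random_binary_data(40, 3, seed = 70)
  m <- train_random_forest(d$X, d$y, n_trees = 4, seed = 71)
  em <- explain_matrix(m, d$X)
  expect_identical(dim(em$phi), c(40L, 3L))
  expect_lt(max(abs(em$base_value + rowSums(em$phi) - predict_proba(m, d$X))),
            1e-8)
  # one instance in, one row out
  em1 <- explain_matrix(m, d$X[7, , drop = FALSE])
  expect_equal(drop(em1$phi), tree_shap(m, d$X[7, ]), ignore_attr = TRUE)
  # constant model: nothing to attribute
  mc <- train_random_forest(d$X, rep(1L, 40), n_trees = 3, seed = 72)
  expect_true(all(explain_matrix(mc, d$X)$phi == 0))
})

test_that("informative features dominate noise features in explanation space", {
  ds <- generate_hypercube_dataset(synthetic_spec(seed = 1))
  yb <- split_supersets(ds$y_subclass, 0:2)
  m <- train_random_forest(ds$X, yb, seed = 101)
  em <- explain_matrix(m, ds$X)
  inf_cols <- match(attr(ds, "informative_features"), colnames(em$phi))
  noise_cols <- match(attr(ds, "noise_features"), colnames(em$phi))
  expect_gt(mean(abs(em$phi[, inf_cols])), 10 * mean(abs(em$phi[, noise_cols])))
})

test_that("explanations round-trip through CSV plus sidecar", {
  d <- random_binary_data(25, 3, seed = 80)
  m <- train_random_forest(d$X, d$y, n_trees = 3, seed = 81)
  em <- explain_matrix(m, d$X)
  f <- withr::local_tempfile(fileext = ".csv")
  write_explanations(em, f)
  back <- read_explanations(f)
  expect_equal(back$phi, em$phi, tolerance = 1e-12)
  expect_equal(back$base_value, em$base_value, tolerance = 1e-12)
})
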