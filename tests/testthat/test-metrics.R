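# the worked four-point example: clusters {0, 1} and {10, 11} on the line
X4 <- matrix(c(0, 1, 10, 11))
lab4 <- c(1, 1, 2, 2)

test_that("Davies-Bouldin matches hand computation and its degenerate cases", {
  expect_equal(davies_bouldin(matrix(c(0, 0.1, 10, 10.1)), lab4), 0.01,
               tolerance = 1e-12)
  # every cluster a single point: zero dispersion everywhere
  expect_equal(davies_bouldin(matrix(c(0, 3, 9)), 1:3), 0)
  # identical centroids with spread are undefined
  expect_error(davies_bouldin(rbind(c(0, 1), c(0, -1), c(0, 2), c(0, -2)),
                              c(1, 1, 2, 2)), "identical centroid")
})

test_that("Calinski-Harabasz matches hand computation and is shift/scale invariant", {
  expect_equal(calinski_harabasz(X4, lab4), 200, tolerance = 1e-12)
  explspace:::with_preserved_seed(1, {
    X <- matrix(rnorm(60), 20, 3)
    lab <- rep(1:4, 5)
  })
  ch <- calinski_harabasz(X, lab)
  expect_equal(calinski_harabasz(X + 7, lab), ch, tolerance = 1e-9)
  expect_equal(calinski_harabasz(X * 3.7, lab), ch, tolerance = 1e-9)
  # coincident points within clusters: +Inf sentinel
  expect_identical(calinski_harabasz(matrix(c(0, 0, 5, 5)), lab4), Inf)
})

test_that("silhouette matches hand computation and stays within [-1, 1]", {
  s <- mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(silhouette_coefficient(X4, lab4), s, tolerance = 1e-12)
  expect_equal(round(s, 4), 0.8997)
  # coincident clusters split arbitrarily score no better than zero
  Xc <- matrix(rep(c(0, 0), 4), ncol = 2, byrow = TRUE)
  expect_lte(silhouette_coefficient(Xc, c(1, 2, 1, 2)), 0)
  explspace:::with_preserved_seed(2, {
    X <- matrix(rnorm(80), 40, 2)
    lab <- sample(3, 40, replace = TRUE)
  })
  expect_true(abs(silhouette_coefficient(X, lab)) <= 1)
})

test_that("AMI is exact on the analytic cases", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_mutual_information(a, a), 1.0)
  expect_equal(adjusted_mutual_information(a, rep(1, 6)), 0.0)
  expect_equal(adjusted_mutual_information(rep(1, 6), a), 0.0)
})

test_that("AMI matches an exhaustive-permutation estimate of the chance correction", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 1, 2, 3, 3, 2)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6L), ]
  emi <- mean(apply(perms, 1, function(pr) mi_nats(a, b[pr])))
  h <- function(z) { p <- table(z) / length(z); -sum(p * log(p)) }
  ami_oracle <- (mi_nats(a, b) - emi) / (mean(c(h(a), h(b))) - emi)
  expect_equal(adjusted_mutual_information(a, b), ami_oracle, tolerance = 1e-10)
  # and with the max normalizer
  ami_max <- (mi_nats(a, b) - emi) / (max(h(a), h(b)) - emi)
  expect_equal(adjusted_mutual_information(a, b, average_method = "max"),
               ami_max, tolerance = 1e-10)
})

test_that("AMI is symmetric and centred at zero against random partitions", {
  explspace:::with_preserved_seed(3, {
    a <- sample(4, 200, replace = TRUE)
    b <- sample(3, 200, replace = TRUE)
  })
  expect_equal(adjusted_mutual_information(a, b),
               adjusted_mutual_information(b, a), tolerance = 1e-12)
  vals <- vapply(1:50, function(s) {
    bb <- explspace:::with_preserved_seed(100 + s, sample(4, 500, replace = TRUE))
    adjusted_mutual_information(rep(1:4, each = 125), bb)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.03)
  expect_error(adjusted_mutual_information(a, b[-1]), "length")
})

test_that("all four metrics are invariant to label renaming and row reordering", {
  explspace:::with_preserved_seed(4, {
    X <- matrix(rnorm(120), 40, 3)
    lab <- sample(3, 40, replace = TRUE)
    part <- sample(3, 40, replace = TRUE)
    perm <- sample(40)
  })
  rename <- c(3L, 1L, 2L)[lab]
  for (f in list(davies_bouldin, calinski_harabasz, silhouette_coefficient)) {
    expect_equal(f(X, rename), f(X, lab), tolerance = 1e-12)
    expect_equal(f(X[perm, ], lab[perm]), f(X, lab), tolerance = 1e-12)
  }
  expect_equal(adjusted_mutual_information(rename, part),
               adjusted_mutual_information(lab, part), tolerance = 1e-12)
  expect_equal(adjusted_mutual_information(lab[perm], part[perm]),
               adjusted_mutual_information(lab, part), tolerance = 1e-12)
})

test_that("indices respond monotonically as two blobs are pulled apart", {
  seps <- c(1, 3, 6, 12)
  vals <- sapply(seps, function(s) {
    b <- make_blobs(25, rbind(c(0, 0), c(s, 0)), sd = 1, seed = 5)
    c(db = davies_bouldin(b$X, b$y), ch = calinski_harabasz(b$X, b$y),
      sil = silhouette_coefficient(b$X, b$y))
  })
  expect_true(all(diff(vals["db", ]) < 0))
  expect_true(all(diff(vals["ch", ]) > 0))
  expect_true(all(diff(vals["sil", ]) > 0))
})
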