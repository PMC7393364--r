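# Independent oracles used across the suite.  Each reimplements, as naively
# as possible, a quantity the package computes by a cleverer route; none of
# them calls into the code path it checks.

# route one instance through an array-form tree by plain iteration
route_tree_value <- function(tree, x) {
  node <- 0L
  repeat {
    i <- node + 1L
    f <- tree$split_feature[i]
    if (f < 0L) return(tree$leaf_value[i])
    node <- if (x[f + 1L] <= tree$split_threshold[i]) tree$children_left[i]
            else tree$children_right[i]
  }
}

# conditional expectation by explicit leaf enumeration: walk every
# root-to-leaf path, multiplying cover fractions at unknown splits and
# routing indicators at known splits
leaf_enum_expected_value <- function(tree, x, known) {
  total <- 0
  walk <- function(node, w) {
    i <- node + 1L
    f <- tree$split_feature[i]
    if (f < 0L) {
      total <<- total + w * tree$leaf_value[i]
      return(invisible())
    }
    l <- tree$children_left[i]; r <- tree$children_right[i]
    if ((f + 1L) %in% known) {
      if (x[f + 1L] <= tree$split_threshold[i]) walk(l, w) else walk(r, w)
    } else {
      walk(l, w * tree$node_cover[l + 1L] / tree$node_cover[i])
      walk(r, w * tree$node_cover[r + 1L] / tree$node_cover[i])
    }
  }
  walk(0L, 1)
  total
}

# greedy Ward agglomeration in O(n^3): at each step merge the pair whose
# union least increases total within-cluster variance
naive_ward_labels <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  sums <- lapply(seq_len(n), function(i) X[i, ])
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))
  while (length(members) > k) {
    m <- length(members)
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        mu_d <- sums[[i]] / sizes[i] - sums[[j]] / sizes[j]
        d <- sum(mu_d^2) * sizes[i] * sizes[j] / (sizes[i] + sizes[j])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    sums[[bi]] <- sums[[bi]] + sums[[bj]]
    sizes[bi] <- sizes[bi] + sizes[bj]
    members[[bi]] <- c(members[[bi]], members[[bj]])
    sums[[bj]] <- NULL; members[[bj]] <- NULL; sizes <- sizes[-bj]
  }
  lab <- integer(n)
  for (c in seq_along(members)) lab[members[[c]]] <- c
  lab
}

# two partitions are the same up to cluster renaming iff their contingency
# table is a (padded) permutation matrix pattern
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# mutual information of two label vectors, natural log
mi_nats <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

# isotropic Gaussian blobs with well-separated centers
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  explspace:::with_preserved_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
  list(X = X, y = rep(seq_len(nrow(centers)), each = n_per))
}

# small random binary-labelled training set for forest fixtures
random_binary_data <- function(n, p, seed) {
  explspace:::with_preserved_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- as.integer(rowSums(X[, seq_len(min(2L, p)), drop = FALSE]) +
                      rnorm(n, sd = 0.5) > 0)
    if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  })
  list(X = X, y = y)
}

# hand-built single-split stump: cover 100 at the root, 50/50 children with
# leaf values 0.2 (left, x <= 0) and 0.8 (right)
stump_ensemble <- function() {
  structure(list(
    trees = list(list(children_left = c(1L, -1L, -1L),
                      children_right = c(2L, -1L, -1L),
                      split_feature = c(0L, -1L, -1L),
                      split_threshold = c(0, NA, NA),
                      leaf_value = c(0.5, 0.2, 0.8),
                      node_cover = c(100, 50, 50))),
    n_features = 1L, base_value = 0.5, n_trees = 1L, feature_names = NULL),
    class = "tree_ensemble")
}
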