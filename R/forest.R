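#' Train a bagged ensemble of binary CART trees
#'
#' Fits the binary diagnostic classifier used throughout the pipeline: each
#' tree is grown on a bootstrap resample (weighted when `sample_weights` are
#' given) by recursive partitioning that maximizes Gini impurity decrease
#' over `mtry` features sampled per node.  Splitting stops at purity,
#' `min_leaf`, or `max_depth`.  The ensemble prediction is the unweighted
#' mean over trees of the positive-class fraction in the reached leaf, so
#' the output is a probability.
#'
#' The fitted trees are held in an array-form interchange representation
#' (parallel arrays per tree, 0-based node and feature indices, `-1` at
#' leaves) that the Shapley attribution code consumes directly and that
#' round-trips losslessly through [serialize_ensemble()].  Ties between
#' candidate splits are broken toward the lowest feature index, then the
#' lowest threshold; thresholds are midpoints between consecutive distinct
#' sorted values and routing is left iff `x <= threshold`.  Identical inputs
#' and seed give a bit-identical ensemble.
#'
#' @param x a [labeled_dataset()] whose subclass labels are already binary,
#'   or a numeric feature matrix.
#' @param y binary labels in `{0,1}` (ignored when `x` is a
#'   `labeled_dataset`).
#' @param n_trees number of trees.
#' @param mtry features sampled per node; default `ceiling(sqrt(p))`.
#' @param min_leaf minimum instances per leaf.
#' @param max_depth maximum tree depth, `NULL` for unlimited.
#' @param sample_weights optional non-negative per-instance weights; the
#'   bootstrap resamples with probability proportional to them, which is
#'   equivalent in expectation to inverse-frequency resampling when the
#'   weights come from [inverse_frequency_weights()].
#' @param seed integer seed for bootstrap and per-node feature sampling.
#' @return an object of class `tree_ensemble`: list of array-form trees plus
#'   `n_features` and `base_value` (the cover-weighted mean leaf value
#'   averaged over trees, i.e. each tree's mean predicted probability over
#'   its own bootstrap sample).
#' @export
train_random_forest <- function(x, y = NULL, n_trees = 100L, mtry = NULL,
                                min_leaf = 1L, max_depth = NULL,
                                sample_weights = NULL, seed = 0L) {
  if (inherits(x, "labeled_dataset")) {
    y <- x$y_subclass
    x <- x$X
  }
  X <- .assert_matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(x)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary in {0, 1}")
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  mtry <- as.integer(mtry)
  if (mtry < 1L || mtry > p) stop("mtry must be in 1..n_features")
  if (!is.null(sample_weights)) {
    if (length(sample_weights) != nrow(X)) stop("sample_weights length mismatch")
    if (any(sample_weights < 0)) stop("sample_weights must be non-negative")
  }
  md <- if (is.null(max_depth)) -1L else as.integer(max_depth)
  n <- nrow(X)
  prob <- if (is.null(sample_weights)) NULL else sample_weights / sum(sample_weights)

  trees <- vector("list", n_trees)
  with_preserved_seed(seed, {
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, n, replace = TRUE, prob = prob)
      trees[[t]] <- .grow_tree_cpp(X, y, idx - 1L, mtry, as.integer(min_leaf), md)
    }
  })

  model <- structure(
    list(trees = trees, n_features = p, base_value = NA_real_,
         n_trees = n_trees, feature_names = colnames(X)),
    class = "tree_ensemble")
  model$base_value <- .ensemble_base_value(model)
  model
}

# v(empty set): mean over trees of the cover-weighted mean leaf value.
# Exact because child covers sum to the parent cover at every internal node.
.ensemble_base_value <- function(model) {
  mean(vapply(model$trees, function(tr) {
    leaf <- tr$children_left < 0L
    sum(tr$leaf_value[leaf] * tr$node_cover[leaf]) / tr$node_cover[1L]
  }, numeric(1)))
}

#' @export
print.tree_ensemble <- function(x, ...) {
  nodes <- vapply(x$trees, function(t) length(t$leaf_value), numeric(1))
  cat("<tree_ensemble> ", x$n_trees, " trees, ", x$n_features,
      " features, base value ", format(x$base_value, digits = 4),
      ", mean ", format(mean(nodes), digits = 4), " nodes/tree\n", sep = "")
  invisible(x)
}

#' Predicted positive-class probability of a tree ensemble
#'
#' Routes each row through every tree (left iff `x[f] <= threshold`) and
#' averages the reached leaf values.
#'
#' @param model a [train_random_forest()] ensemble.
#' @param X numeric matrix with `model$n_features` columns.
#' @param per_tree if `TRUE`, return the `n x n_trees` matrix of per-tree
#'   leaf values instead of their row means.
#' @return numeric vector of probabilities in `[0, 1]`, or a matrix when
#'   `per_tree = TRUE`.
#' @export
predict_proba <- function(model, X, per_tree = FALSE) {
  stopifnot(inherits(model, "tree_ensemble"))
  X <- .assert_matrix(X)
  if (ncol(X) != model$n_features)
    stop("X has ", ncol(X), " columns; model expects ", model$n_features)
  P <- .predict_trees_cpp(model$trees, X)
  if (per_tree) P else rowMeans(P)
}

# ---------------------------------------------------------------------------
# JSON interchange: schema documented in the serialize_ensemble() help page.
# ---------------------------------------------------------------------------

#' Serialize a tree ensemble to JSON (and back)
#'
#' The document is a single JSON object:
#' \preformatted{
#' {
#'   "format": "explspace_ensemble", "version": 1,
#'   "n_features": <int>, "base_value": <real>,
#'   "trees": [ { "children_left": [...], "children_right": [...],
#'                "split_feature": [...], "split_threshold": [...],
#'                "leaf_value": [...], "node_cover": [...] }, ... ]
#' }
#' }
#' Node and feature indices are 0-based; `-1` marks a leaf in the children
#' and `split_feature` arrays and `split_threshold` is `null` at leaves.
#' Numbers are written at full precision, so the round trip reproduces
#' identical arrays and identical predictions.  `deserialize_ensemble`
#' validates the structural invariants (two children or none, acyclicity and
#' reachability, leaf values in `[0, 1]`, child covers summing to the parent
#' cover) and reports violations with the offending tree and node index.
#'
#' @param model a `tree_ensemble`.
#' @param txt JSON text produced by `serialize_ensemble`.
#' @return `serialize_ensemble` returns a JSON string; `deserialize_ensemble`
#'   a `tree_ensemble`.
#' @export
serialize_ensemble <- function(model) {
  stopifnot(inherits(model, "tree_ensemble"))
  doc <- list(format = "explspace_ensemble", version = 1L,
              n_features = model$n_features, base_value = model$base_value,
              trees = lapply(model$trees, function(tr) {
                tr[c("children_left", "children_right", "split_feature",
                     "split_threshold", "leaf_value", "node_cover")]
              }))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), na = "null"))
}

#' @rdname serialize_ensemble
#' @export
deserialize_ensemble <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "explspace_ensemble")
    stop("not an explspace_ensemble document")
  trees <- doc$trees
  if (is.data.frame(trees)) trees <- split(trees, seq_len(nrow(trees)))
  trees <- lapply(seq_along(trees), function(i) {
    tr <- as.list(trees[[i]])
    list(children_left = as.integer(unlist(tr$children_left)),
         children_right = as.integer(unlist(tr$children_right)),
         split_feature = as.integer(unlist(tr$split_feature)),
         split_threshold = as.numeric(unlist(tr$split_threshold)),
         leaf_value = as.numeric(unlist(tr$leaf_value)),
         node_cover = as.numeric(unlist(tr$node_cover)))
  })
  model <- structure(
    list(trees = trees, n_features = as.integer(doc$n_features),
         base_value = as.numeric(doc$base_value),
         n_trees = length(trees), feature_names = NULL),
    class = "tree_ensemble")
  validate_ensemble(model)
  model
}

#' Validate the structural invariants of a tree ensemble
#'
#' Checks, for every tree: equal array lengths; every node has either two
#' children or none; children indices in range and forming a tree (each
#' non-root node reachable from exactly one parent); leaf values within
#' `[0, 1]`; split features below `n_features`; and cover conservation
#' (child covers summing to the parent cover, within relative tolerance
#' `tol`).  Violations raise an error naming the tree and node.
#'
#' @param model a `tree_ensemble`.
#' @param tol relative tolerance for cover conservation.
#' @return `model`, invisibly.
#' @export
validate_ensemble <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "tree_ensemble"))
  for (ti in seq_along(model$trees)) {
    tr <- model$trees[[ti]]
    nn <- length(tr$children_left)
    lens <- lengths(tr[c("children_right", "split_feature", "split_threshold",
                         "leaf_value", "node_cover")])
    if (any(lens != nn))
      stop("tree ", ti, ": parallel arrays of unequal length")
    bad <- function(node, why) stop("tree ", ti, ", node ", node, ": ", why)
    parents <- integer(nn)
    for (i in seq_len(nn)) {
      l <- tr$children_left[i]; r <- tr$children_right[i]
      if ((l < 0L) != (r < 0L)) bad(i - 1L, "one child only")
      if (l >= 0L) {
        if (l >= nn || r >= nn) bad(i - 1L, "child index out of range")
        if (l == i - 1L || r == i - 1L) bad(i - 1L, "self-referencing child")
        parents[l + 1L] <- parents[l + 1L] + 1L
        parents[r + 1L] <- parents[r + 1L] + 1L
        if (tr$split_feature[i] < 0L || tr$split_feature[i] >= model$n_features)
          bad(i - 1L, "split feature out of range")
        s <- tr$node_cover[l + 1L] + tr$node_cover[r + 1L]
        if (abs(s - tr$node_cover[i]) > tol * max(1, abs(tr$node_cover[i])))
          bad(i - 1L, sprintf("child covers (%g) do not sum to parent cover (%g)",
                              s, tr$node_cover[i]))
      }
      if (is.na(tr$leaf_value[i]) || tr$leaf_value[i] < 0 || tr$leaf_value[i] > 1)
        bad(i - 1L, "leaf_value outside [0, 1]")
      if (is.na(tr$node_cover[i]) || tr$node_cover[i] < 0)
        bad(i - 1L, "negative node cover")
    }
    if (parents[1L] != 0L) bad(0L, "root has a parent")
    if (nn > 1L && any(parents[-1L] != 1L))
      bad(which(parents[-1L] != 1L)[1L], "node not reachable exactly once")
  }
  invisible(model)
}
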