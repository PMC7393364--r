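#' Conditional expectation of a tree given a feature subset
#'
#' Path-dependent semantics: at a split on a *known* feature the evaluation
#' follows the branch `x` routes to; at a split on an unknown feature it
#' returns the cover-weighted average of the two children; at a leaf it
#' returns the leaf value.  This is the value function `v(S)` underlying the
#' tree Shapley attributions.
#'
#' @param tree one array-form tree (an element of `model$trees`).
#' @param x numeric feature vector.
#' @param known integer vector of known feature positions (1-based column
#'   positions of `x`); `integer(0)` for the unconditional expectation.
#' @return the conditional expectation, a single real.
#' @export
tree_expected_value <- function(tree, x, known = integer(0)) {
  known <- as.integer(known)
  rec <- function(node) {
    i <- node + 1L
    f <- tree$split_feature[i]
    if (f < 0L) return(tree$leaf_value[i])
    if ((f + 1L) %in% known) {
      if (x[f + 1L] <= tree$split_threshold[i]) rec(tree$children_left[i])
      else rec(tree$children_right[i])
    } else {
      l <- tree$children_left[i]; r <- tree$children_right[i]
      (tree$node_cover[l + 1L] * rec(l) + tree$node_cover[r + 1L] * rec(r)) /
        tree$node_cover[i]
    }
  }
  rec(0L)
}

#' Exact Shapley attributions by subset enumeration
#'
#' The defining sum: for each feature j,
#' `phi_j = sum over S subset of F\\{j} of |S|! (p-|S|-1)! / p! * (v(S+j) - v(S))`
#' with `v(S)` the mean over trees of [tree_expected_value()].  Exponential
#' in the number of features; intended as the independent oracle for
#' [tree_shap()] on small models.  By the efficiency axiom
#' `sum(phi) = v(F) - v(empty)`.
#'
#' @param model a `tree_ensemble`.
#' @param x numeric feature vector.
#' @param allow_large set `TRUE` to override the `p <= 12` cost guard.
#' @return numeric attribution vector of length `p`.
#' @export
brute_force_shap <- function(model, x, allow_large = FALSE) {
  stopifnot(inherits(model, "tree_ensemble"))
  p <- model$n_features
  if (length(x) != p) stop("x has length ", length(x), "; model expects ", p)
  if (p > 12 && !allow_large)
    stop("p = ", p, " > 12: subset enumeration needs 2^p evaluations; ",
         "pass allow_large = TRUE to override")
  masks <- 0:(2^p - 1L)
  bits <- vapply(seq_len(p),
                 function(j) bitwAnd(bitwShiftR(masks, j - 1L), 1L) == 1L,
                 logical(length(masks)))
  size <- rowSums(bits)
  v <- vapply(masks + 1L, function(m) {
    known <- which(bits[m, ])
    mean(vapply(model$trees, tree_expected_value, numeric(1), x = x, known = known))
  }, numeric(1))
  lfact <- lfactorial(0:p)
  # weight of a subset of size s: s! (p-s-1)! / p!
  w_by_size <- exp(lfact[seq_len(p)] + lfact[rev(seq_len(p))] - lfact[p + 1L])
  phi <- numeric(p)
  for (j in seq_len(p)) {
    jb <- bitwShiftL(1L, j - 1L)
    without <- which(!bits[, j])  # mask + 1 for masks excluding j
    m0 <- masks[without]
    phi[j] <- sum(w_by_size[size[without] + 1L] *
                    (v[bitwOr(m0, jb) + 1L] - v[m0 + 1L]))
  }
  phi
}

#' Polynomial-time tree Shapley attributions
#'
#' Path-dependent TreeSHAP: computes, per tree, the exact Shapley values of
#' the conditional-expectation game defined by [tree_expected_value()] in
#' time polynomial in the number of leaves and depth, then averages over
#' trees.  Agrees with [brute_force_shap()] to numerical precision wherever
#' the oracle is feasible.
#'
#' @param model a `tree_ensemble`.
#' @param x numeric feature vector.
#' @return numeric attribution vector of length `p`.
#' @export
tree_shap <- function(model, x) {
  stopifnot(inherits(model, "tree_ensemble"))
  if (length(x) != model$n_features)
    stop("x has length ", length(x), "; model expects ", model$n_features)
  drop(.tree_shap_cpp(model$trees, matrix(as.numeric(x), nrow = 1L)))
}

#' Explain a set of instances: the transformation into explanation space
#'
#' Row i of the returned matrix is `tree_shap(model, X[i, ])`; the base
#' value is the unconditional expectation `v(empty)`.  Local accuracy --
#' `base_value + rowSums(phi)` equal to the predicted probability -- is
#' verified for every row and a violation beyond `1e-8` is an error.
#'
#' @param model a `tree_ensemble`.
#' @param X numeric matrix with `model$n_features` columns.
#' @param instance_ids optional row identifiers (default: rownames or 1..n).
#' @return an object of class `explanation_matrix`: `phi` (n x p attribution
#'   matrix, same dimensionality as the feature space), `base_value`,
#'   `instance_ids`, `feature_names`.
#' @export
explain_matrix <- function(model, X, instance_ids = NULL) {
  stopifnot(inherits(model, "tree_ensemble"))
  X <- .assert_matrix(X)
  if (ncol(X) != model$n_features)
    stop("X has ", ncol(X), " columns; model expects ", model$n_features)
  phi <- .tree_shap_cpp(model$trees, X)
  pred <- predict_proba(model, X)
  err <- max(abs(model$base_value + rowSums(phi) - pred))
  if (err > 1e-8)
    stop("local accuracy violated: max |base + sum(phi) - prediction| = ",
         format(err))
  if (is.null(instance_ids)) {
    instance_ids <- rownames(X)
    if (is.null(instance_ids)) instance_ids <- as.character(seq_len(nrow(X)))
  }
  fn <- model$feature_names
  if (is.null(fn)) fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)) - 1L)
  colnames(phi) <- fn
  rownames(phi) <- instance_ids
  structure(list(phi = phi, base_value = model$base_value,
                 instance_ids = instance_ids, feature_names = fn),
            class = "explanation_matrix")
}

#' @export
print.explanation_matrix <- function(x, ...) {
  cat("<explanation_matrix> ", nrow(x$phi), " instances x ", ncol(x$phi),
      " features, base value ", format(x$base_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write / read an explanation matrix
#'
#' CSV with an `instance_id` column plus one column per feature; the base
#' value (and column names) go to a JSON sidecar at `paste0(path, ".json")`.
#'
#' @param em an [explain_matrix()] result.
#' @param path CSV path; sidecar written next to it.
#' @return `write_explanations` returns `path` invisibly;
#'   `read_explanations` an `explanation_matrix`.
#' @export
write_explanations <- function(em, path) {
  stopifnot(inherits(em, "explanation_matrix"))
  df <- data.frame(instance_id = em$instance_ids, em$phi,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(base_value = em$base_value,
                            feature_names = em$feature_names),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_explanations
#' @export
read_explanations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  ids <- as.character(df$instance_id)
  phi <- as.matrix(df[setdiff(names(df), "instance_id")])
  rownames(phi) <- ids
  structure(list(phi = phi, base_value = as.numeric(side$base_value),
                 instance_ids = ids, feature_names = colnames(phi)),
            class = "explanation_matrix")
}
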