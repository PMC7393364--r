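#' Specification for the hypercube-cluster synthetic benchmark
#'
#' Describes a labelled classification dataset in which each class occupies
#' one vertex of a hypercube in an informative subspace, in the style of the
#' Madelon generator family: `n_informative` coordinates carry the class
#' structure (one Gaussian cluster per class, centred on a distinct vertex of
#' the hypercube with half-edge `class_sep`), `n_redundant` features are fixed
#' random linear combinations of the informative ones, and the remaining
#' features are independent standard Gaussian noise.
#'
#' By default each class cluster additionally receives a random covariance:
#' its informative-noise block is right-multiplied by a class-specific random
#' matrix with entries uniform in `[-1, 1]` before the vertex is added
#' (`cluster_covariance = TRUE`), as in the generator family this emulates.
#' The anisotropic, class-specific cluster shapes are what make the raw
#' feature space hard for Euclidean cluster analysis while leaving the class
#' regions learnable by a flexible classifier.
#'
#' The defaults describe the benchmark regime used throughout the package:
#' 16 classes on the vertices of a four-dimensional hypercube, 50 features,
#' 100 samples per class.  `class_sep = 2.0` with unit (pre-mixing)
#' within-cluster noise makes the binary superset task solvable by a bagged
#' tree ensemble (held-out accuracy above 0.9 with margin) while leaving
#' Euclidean distances in the full feature space dominated by the 42 noise
#' coordinates.
#'
#' @param n_samples total number of instances.
#' @param n_classes number of subclasses; requires `2^n_informative >= n_classes`
#'   so that every class gets a distinct vertex.
#' @param n_features total number of feature columns.
#' @param n_informative dimension of the hypercube subspace.
#' @param n_redundant number of features that are random linear combinations
#'   of the informative ones.
#' @param class_sep half-edge of the hypercube: vertices lie in
#'   `{-class_sep, +class_sep}^n_informative`.
#' @param within_cluster_sd standard deviation of the Gaussian noise around
#'   each class vertex (pre-mixing scale when `cluster_covariance` is on).
#' @param cluster_covariance if `TRUE` (default), transform each class's
#'   informative noise by a class-specific random matrix with entries
#'   uniform in `[-1, 1]`, giving every cluster its own anisotropic shape.
#' @param seed integer seed; identical specs generate bit-identical datasets.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_hypercube_dataset()]
#' @export
synthetic_spec <- function(n_samples = 1600L, n_classes = 16L, n_features = 50L,
                           n_informative = 4L, n_redundant = 4L,
                           class_sep = 2.0, within_cluster_sd = 1.0,
                           cluster_covariance = TRUE, seed = 0L) {
  n_samples <- as.integer(n_samples)
  n_classes <- as.integer(n_classes)
  n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative)
  n_redundant <- as.integer(n_redundant)
  if (n_samples < 1L || n_classes < 1L || n_features < 1L || n_informative < 1L)
    stop("n_samples, n_classes, n_features and n_informative must be positive")
  if (n_redundant < 0L) stop("n_redundant must be non-negative")
  if (class_sep <= 0) stop("class_sep must be positive")
  if (within_cluster_sd < 0) stop("within_cluster_sd must be non-negative")
  if (2^n_informative < n_classes)
    stop("2^n_informative (", 2^n_informative, ") < n_classes (", n_classes,
         "): each class needs a distinct hypercube vertex")
  if (n_informative + n_redundant > n_features)
    stop("n_informative + n_redundant exceeds n_features")
  structure(
    list(n_samples = n_samples, n_classes = n_classes, n_features = n_features,
         n_informative = n_informative, n_redundant = n_redundant,
         class_sep = class_sep, within_cluster_sd = within_cluster_sd,
         cluster_covariance = isTRUE(cluster_covariance),
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Construct a labelled dataset
#'
#' Lightweight container pairing a numeric feature matrix with one subclass
#' label per row.  All pipeline stages consume this form; user data read from
#' CSV/TSV via [read_dataset_csv()] arrives in it too.
#'
#' @param X numeric matrix, instances in rows.
#' @param y_subclass integer-like subclass label per row.
#' @param feature_names optional column names; defaults to existing
#'   `colnames(X)` or `f0..f{p-1}`.
#' @return an object of class `labeled_dataset` with elements `X`,
#'   `y_subclass`, `feature_names`.
#' @export
labeled_dataset <- function(X, y_subclass, feature_names = NULL) {
  X <- .assert_matrix(X)
  if (nrow(X) != length(y_subclass))
    stop("row count of X (", nrow(X), ") != length of y_subclass (",
         length(y_subclass), ")")
  if (anyNA(y_subclass)) stop("y_subclass contains missing values")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)) - 1L)
  }
  if (length(feature_names) != ncol(X))
    stop("feature_names length != number of columns")
  colnames(X) <- feature_names
  if (is.numeric(y_subclass)) {
    y <- as.integer(y_subclass)
    if (any(y != y_subclass)) stop("y_subclass must be integer-valued")
  } else {
    # non-numeric labels are coded 0..k-1 in level order; levels retained
    f <- as.factor(y_subclass)
    y <- as.integer(f) - 1L
    attr(y, "levels") <- levels(f)
  }
  structure(list(X = X, y_subclass = y, feature_names = feature_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$X), " instances x ", ncol(x$X),
      " features, ", length(unique(x$y_subclass)), " subclasses\n", sep = "")
  invisible(x)
}

#' Generate a hypercube-cluster synthetic dataset
#'
#' Deterministically (under `spec$seed`) assigns each class a distinct vertex
#' of the `{-class_sep, +class_sep}^n_informative` hypercube (vertices
#' enumerated in binary-counting order, assignment shuffled under the seed),
#' draws instances as the class vertex plus Gaussian noise in the
#' informative coordinates (transformed per class by a random covariance
#' matrix when `spec$cluster_covariance` is on), appends redundant features
#' (fixed random linear combinations of the informative columns, weights
#' uniform in `[-1, 1]`) and pure-noise features, and randomly permutes the
#' column order.  The permutation travels with the
#' column names: column `f{j}` is always the j-th *generated* feature, so
#' `f0..f{n_informative-1}` are the informative ones wherever they land.
#'
#' Class sizes are as equal as integer division allows (the first
#' `n_samples %% n_classes` classes get one extra instance).
#'
#' @param spec a [synthetic_spec()].
#' @return a [labeled_dataset()] with subclass labels `0..n_classes-1` and
#'   attributes `spec`, `vertices` (the class-by-informative vertex table),
#'   `informative_features`, `redundant_features`, `noise_features`.
#' @export
generate_hypercube_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  n <- spec$n_samples; K <- spec$n_classes; p <- spec$n_features
  ni <- spec$n_informative; nr <- spec$n_redundant
  nn <- p - ni - nr

  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  y <- rep(seq_len(K) - 1L, times = sizes)

  with_preserved_seed(spec$seed, {
    # vertices in binary-counting order, shuffled assignment to classes
    bits <- t(vapply(seq_len(K) - 1L,
                     function(c) as.integer(bitwAnd(bitwShiftR(c, seq_len(ni) - 1L), 1L)),
                     integer(ni)))
    vertices <- (2 * bits - 1) * spec$class_sep
    vertices <- vertices[sample.int(K), , drop = FALSE]

    E <- matrix(rnorm(n * ni, sd = spec$within_cluster_sd), n, ni)
    if (spec$cluster_covariance) {
      for (c in seq_len(K) - 1L) {
        A <- matrix(stats::runif(ni * ni, -1, 1), ni, ni)
        rows <- which(y == c)
        E[rows, ] <- E[rows, , drop = FALSE] %*% A
      }
    }
    XI <- vertices[y + 1L, , drop = FALSE] + E
    W <- matrix(stats::runif(ni * nr, -1, 1), ni, nr)
    XR <- XI %*% W
    XN <- matrix(rnorm(n * nn), n, nn)
    X <- cbind(XI, XR, XN)
    colnames(X) <- paste0("f", seq_len(p) - 1L)
    perm <- sample.int(p)
    X <- X[, perm, drop = FALSE]
  })

  ds <- labeled_dataset(X, y)
  attr(ds, "spec") <- spec
  attr(ds, "vertices") <- vertices
  attr(ds, "informative_features") <- paste0("f", seq_len(ni) - 1L)
  attr(ds, "redundant_features") <- if (nr > 0) paste0("f", ni + seq_len(nr) - 1L) else character()
  attr(ds, "noise_features") <- if (nn > 0) paste0("f", ni + nr + seq_len(nn) - 1L) else character()
  ds
}

#' Write / read a labelled dataset as CSV
#'
#' The on-disk dialect is a header row with one `label` column followed by
#' the feature columns.  The reader accepts any labelled feature table in
#' that dialect with a configurable label-column name; remaining columns are
#' taken as features in file order.
#'
#' @param data a [labeled_dataset()].
#' @param path file path.
#' @param label_col name of the label column (default `"label"`).
#' @param sep field separator; `","` for CSV, `"\t"` for TSV.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a [labeled_dataset()].
#' @export
write_dataset_csv <- function(data, path, label_col = "label", sep = ",") {
  stopifnot(inherits(data, "labeled_dataset"))
  df <- data.frame(data$y_subclass, data$X, check.names = FALSE)
  names(df)[1] <- label_col
  utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, label_col = "label", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found in ", path)
  y <- df[[label_col]]
  X <- as.matrix(df[setdiff(names(df), label_col)])
  labeled_dataset(X, y)
}
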