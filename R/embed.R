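#' Principal component reduction
#'
#' Projects the column-centred matrix onto its top singular directions,
#' ordered by decreasing explained variance.  The sign of each component is
#' fixed so that its largest-magnitude loading is positive, making the
#' output deterministic.
#'
#' @param X numeric matrix.
#' @param n_components number of components, at most `min(n, p)`.
#' @return an object of class `embedding` with `coords`
#'   (`n x n_components`), `method = "pca"`, and `params` containing the
#'   component standard deviations and explained-variance ratios.
#' @export
pca_reduce <- function(X, n_components = 2L) {
  X <- .assert_matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 rows for PCA")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n, p))
    stop("n_components must be in 1..min(n, p)")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 0L, nv = n_components)
  V <- sv$v
  for (j in seq_len(n_components)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  coords <- Xc %*% V
  colnames(coords) <- paste0("PC", seq_len(n_components))
  var_all <- sv$d^2 / (n - 1)
  structure(list(coords = coords, method = "pca",
                 params = list(sdev = sqrt(var_all[seq_len(n_components)]),
                               var_explained = var_all[seq_len(n_components)] /
                                 sum(var_all),
                               rotation = V),
                 seed = NA_integer_),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("<embedding> method=", x$method, ", ", nrow(x$coords), " x ",
      ncol(x$coords), "\n", sep = "")
  invisible(x)
}

#' Dimensionality-reduction adapter
#'
#' Applies one of the supported reducers identically to whichever space
#' (feature or explanation) it is given.  `"none"` returns the input
#' unchanged, `"pca"` delegates to [pca_reduce()], `"isomap"` wraps
#' [vegan::isomap()] (classical MDS on geodesic distances over a
#' k-nearest-neighbour graph; if the graph is fragmented, k is increased
#' until it connects, and the value used is recorded in `params`),
#' `"tsne"` runs the package's exact (non-approximate) t-SNE optimizer.
#' All reduced methods return two columns by default and are deterministic
#' under a fixed `seed`.
#'
#' @param X numeric matrix.
#' @param method one of `"none"`, `"pca"`, `"isomap"`, `"tsne"`.
#' @param n_components output dimensionality for the reduced methods.
#' @param seed integer seed (used by t-SNE's random initialization; recorded
#'   for the deterministic methods).
#' @param isomap_k neighbourhood size for Isomap.
#' @param tsne_perplexity,tsne_eta,tsne_n_iter t-SNE settings: perplexity,
#'   learning rate, iteration count.
#' @return an `embedding`.
#' @export
reduce_dim <- function(X, method = c("none", "pca", "isomap", "tsne"),
                       n_components = 2L, seed = 0L, isomap_k = 5L,
                       tsne_perplexity = 30, tsne_eta = 200,
                       tsne_n_iter = 1000L) {
  method <- match.arg(method)
  X <- .assert_matrix(X)
  switch(method,
    none = structure(list(coords = X, method = "none", params = list(),
                          seed = as.integer(seed)),
                     class = "embedding"),
    pca = {
      e <- pca_reduce(X, n_components)
      e$seed <- as.integer(seed)
      e
    },
    isomap = .isomap_reduce(X, n_components, isomap_k, seed),
    tsne = .tsne_reduce(X, n_components, tsne_perplexity, tsne_eta,
                        tsne_n_iter, seed))
}

.isomap_reduce <- function(X, n_components, k, seed) {
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows for Isomap")
  d <- stats::dist(X)
  k <- max(1L, min(as.integer(k), n - 1L))
  coords <- NULL
  while (is.null(coords) && k < n) {
    coords <- tryCatch(
      vegan::isomap(d, ndim = n_components, k = k)$points,
      error = function(e) NULL)
    if (is.null(coords)) k <- min(n - 1L, k * 2L)
  }
  if (is.null(coords)) stop("Isomap failed even with a complete graph")
  # fix per-axis sign so the largest-magnitude coordinate is positive
  for (j in seq_len(ncol(coords))) {
    i0 <- which.max(abs(coords[, j]))
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(list(coords = coords, method = "isomap",
                 params = list(k = k), seed = as.integer(seed)),
            class = "embedding")
}

# ---------------------------------------------------------------------------
# Exact t-SNE.  O(n^2) per iteration; adequate for the few hundred instances
# the benchmark embeds.  Conditional p_{j|i} are calibrated to the target
# perplexity by bisection on the precision beta_i, then symmetrized and
# normalized.  Optimization uses early exaggeration (factor 12 for the first
# 250 iterations), momentum 0.5 switching to 0.8 at iteration 250, and
# per-coordinate adaptive gains -- the long-standing reference schedule.
# ---------------------------------------------------------------------------

.tsne_cond_p <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    Di <- D2[i, -i]
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (it in seq_len(max_iter)) {
      Pi <- exp(-Di * beta)
      s <- sum(Pi)
      if (s == 0) { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2; next }
      H <- log(s) + beta * sum(Di * Pi) / s
      if (abs(H - logU) < tol) break
      if (H > logU) { # entropy too high -> sharpen
        bmin <- beta
        beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2
      } else {
        bmax <- beta
        beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2
      }
    }
    Pi <- exp(-Di * beta)
    Pi <- Pi / sum(Pi)
    P[i, -i] <- Pi
  }
  P <- P + t(P)
  P / sum(P)
}

.tsne_reduce <- function(X, n_components = 2L, perplexity = 30, eta = 200,
                         n_iter = 1000L, seed = 0L) {
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 rows for t-SNE")
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- .tsne_cond_p(as.matrix(stats::dist(X))^2, perplexity)
  P <- pmax(P, 1e-12)
  with_preserved_seed(seed,
    Y <- matrix(rnorm(n * n_components, sd = 1e-4), n, n_components))
  update <- matrix(0, n, n_components)
  gains <- matrix(1, n, n_components)
  exag_until <- min(250L, n_iter)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_until) P * 12 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (rowSums(L) * Y - L %*% Y)
    mom <- if (it < 250L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(update), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    update <- mom * update - eta * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  colnames(Y) <- paste0("dim", seq_len(n_components))
  structure(list(coords = Y, method = "tsne",
                 params = list(perplexity = perplexity, eta = eta,
                               n_iter = as.integer(n_iter)),
                 seed = as.integer(seed)),
            class = "embedding")
}

#' Ward agglomerative clustering
#'
#' Bottom-up merging that at each step joins the pair of clusters whose
#' union minimally increases total within-cluster variance (Ward's
#' criterion, computed through the standard Lance-Williams recurrence on
#' Euclidean distances via [stats::hclust()] with `method = "ward.D2"`),
#' cut at `k` clusters.
#'
#' @param X numeric matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @return an object of class `cluster_partition` with integer `labels`
#'   in `1..k` and `k`.
#' @export
ward_agglomerative <- function(X, k) {
  X <- .assert_matrix(X)
  n <- nrow(X)
  if (n < 1L) stop("empty input")
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in 1..n")
  labels <- if (k == n) {
    seq_len(n)
  } else if (k == 1L) {
    rep(1L, n)
  } else {
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    unname(stats::cutree(hc, k = k))
  }
  cluster_partition(labels, k)
}

#' Construct a cluster partition
#'
#' @param labels integer cluster index per instance.
#' @param k number of clusters; defaults to the number of distinct labels.
#'   Every cluster `1..k` must be non-empty.
#' @return an object of class `cluster_partition`.
#' @export
cluster_partition <- function(labels, k = NULL) {
  labels <- as.integer(as.factor(labels))
  if (is.null(k)) k <- max(labels)
  k <- as.integer(k)
  if (length(unique(labels)) != k)
    stop("partition has ", length(unique(labels)), " non-empty clusters, not k = ", k)
  structure(list(labels = labels, k = k), class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> ", length(x$labels), " instances in ", x$k,
      " clusters\n", sep = "")
  invisible(x)
}

# Accept either a cluster_partition or a raw label vector.
.labels <- function(labels) {
  if (inherits(labels, "cluster_partition")) labels$labels
  else as.integer(as.factor(labels))
}
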