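#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case similarity to another cluster:
#' `DB = (1/k) * sum_i max_{j != i} (s_i + s_j) / d(mu_i, mu_j)`, where
#' `s_i` is the mean Euclidean distance of cluster-i points to their
#' centroid `mu_i`.  Lower is better; zero when every cluster is a single
#' point at a distinct location.
#'
#' @param X numeric matrix.
#' @param labels a `cluster_partition` or label vector with `k >= 2`
#'   non-empty clusters.
#' @return the index, a non-negative real.
#' @export
davies_bouldin <- function(X, labels) {
  X <- .assert_matrix(X)
  lab <- .labels(labels)
  if (length(lab) != nrow(X)) stop("labels length != nrow(X)")
  lv <- sort(unique(lab))
  k <- length(lv)
  if (k < 2L) stop("Davies-Bouldin requires at least 2 clusters")
  cent <- matrix(0, k, ncol(X))
  for (i in seq_along(lv)) cent[i, ] <- colMeans(X[lab == lv[i], , drop = FALSE])
  s <- vapply(seq_along(lv), function(i) {
    Xi <- X[lab == lv[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2L, cent[i, ])^2)))
  }, numeric(1))
  dmat <- as.matrix(stats::dist(cent))
  off <- dmat[upper.tri(dmat)]
  if (any(off == 0))
    stop("two clusters share an identical centroid: pairwise similarity is ",
         "undefined (division by zero)")
  R <- outer(s, s, "+") / dmat
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Calinski-Harabasz index
#'
#' Degree-of-freedom-normalized ratio of between-cluster to within-cluster
#' dispersion: `CH = (B / (k - 1)) / (W / (n - k))` with
#' `B = sum_i n_i ||mu_i - mu||^2` and
#' `W = sum_i sum_{x in C_i} ||x - mu_i||^2`.  Higher is better.  When every
#' point coincides with its centroid (`W = 0`) the index is reported as
#' `Inf`.
#'
#' @inheritParams davies_bouldin
#' @return the index, a non-negative real (possibly `Inf`).
#' @export
calinski_harabasz <- function(X, labels) {
  X <- .assert_matrix(X)
  lab <- .labels(labels)
  if (length(lab) != nrow(X)) stop("labels length != nrow(X)")
  n <- nrow(X)
  lv <- sort(unique(lab))
  k <- length(lv)
  if (k < 2L || k > n - 1L) stop("Calinski-Harabasz requires 2 <= k <= n - 1")
  mu <- colMeans(X)
  B <- 0; W <- 0
  for (g in lv) {
    Xi <- X[lab == g, , drop = FALSE]
    mi <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((mi - mu)^2)
    W <- W + sum(sweep(Xi, 2L, mi)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Mean silhouette coefficient
#'
#' Per sample, `s = (b - a) / max(a, b)` where `a` is the mean distance to
#' the other members of its own cluster and `b` the smallest mean distance
#' to the members of any other cluster; points in singleton clusters score
#' 0, as does a point with `a = b = 0`.  The index is the mean over samples
#' and always lies in `[-1, 1]`.
#'
#' @inheritParams davies_bouldin
#' @return the mean silhouette, in `[-1, 1]`.
#' @export
silhouette_coefficient <- function(X, labels) {
  X <- .assert_matrix(X)
  lab <- .labels(labels)
  n <- nrow(X)
  if (length(lab) != n) stop("labels length != nrow(X)")
  lv <- sort(unique(lab))
  k <- length(lv)
  if (k < 2L || k > n - 1L) stop("silhouette requires 2 <= k <= n - 1")
  D <- as.matrix(stats::dist(X))
  sizes <- table(factor(lab, levels = lv))
  # mean distance from each point to each cluster
  md <- vapply(lv, function(g) rowSums(D[, lab == g, drop = FALSE]),
               numeric(n))
  md <- sweep(md, 2L, as.numeric(sizes), "/")
  s <- numeric(n)
  for (i in seq_len(n)) {
    gi <- match(lab[i], lv)
    ni <- sizes[gi]
    if (ni == 1L) { s[i] <- 0; next }
    a <- md[i, gi] * ni / (ni - 1)  # exclude self
    b <- min(md[i, -gi])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected agreement:
#' `AMI = (MI - E[MI]) / (norm(H_a, H_b) - E[MI])`, where MI is the mutual
#' information of the contingency table (natural logarithms; AMI itself is
#' base-invariant), `E[MI]` its exact expectation under the permutation
#' (hypergeometric) model computed by summation over all admissible cell
#' counts, and the normalizer is the arithmetic mean of the partition
#' entropies by default (`average_method = "max"` selects the maximum
#' instead).  Identical partitions score 1; a partition carrying no
#' information about the other scores approximately 0, and the expectation
#' against random partitions is 0 by construction.
#'
#' @param a,b `cluster_partition`s or label vectors of equal length.
#' @param average_method entropy normalizer: `"mean"` (default) or `"max"`.
#' @return the AMI, a real `<= 1`.
#' @export
adjusted_mutual_information <- function(a, b, average_method = c("mean", "max")) {
  average_method <- match.arg(average_method)
  la <- .labels(a)
  lb <- .labels(b)
  if (length(la) != length(lb)) stop("partitions have different lengths")
  n <- length(la)
  if (n == 0L) stop("empty partitions")
  tab <- table(la, lb)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  # both partitions trivial (single cluster, or all singletons): perfect match
  if ((length(ai) == 1L && length(bj) == 1L) ||
      (length(ai) == n && length(bj) == n)) return(1.0)
  pij <- tab / n
  nz <- tab > 0
  mi <- sum(pij[nz] * log(pij[nz] / (outer(ai, bj)[nz] / n^2)))
  ha <- -sum((ai / n) * log(ai / n))
  hb <- -sum((bj / n) * log(bj / n))
  emi <- .expected_mi(ai, bj, n)
  norm <- if (average_method == "mean") mean(c(ha, hb)) else max(ha, hb)
  denom <- norm - emi
  if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps * sign(denom + (denom == 0))
  (mi - emi) / denom
}

# Exact E[MI] under the permutation model: for each (i, j) margin pair, sum
# the hypergeometric probability of each admissible cell count n_ij times
# its MI contribution.
.expected_mi <- function(ai, bj, n) {
  lg <- lgamma(seq_len(n + 1))  # lg[m + 1] = log(m!)
  lfac <- function(m) lg[m + 1]
  emi <- 0
  for (a in ai) {
    for (b in bj) {
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lfac(a) + lfac(b) + lfac(n - a) + lfac(n - b) - lfac(n) -
        lfac(nij) - lfac(a - nij) - lfac(b - nij) - lfac(n - a - b + nij)
      emi <- emi + sum((nij / n) * log(n * nij / (a * b)) * exp(lp))
    }
  }
  emi
}

# Assemble one row of the metric grid for a given embedding + partitions.
.metric_cell <- function(coords, reference_labels, partition) {
  list(davies_bouldin = davies_bouldin(coords, reference_labels),
       calinski_harabasz = calinski_harabasz(coords, reference_labels),
       silhouette = silhouette_coefficient(coords, reference_labels),
       adjusted_mi = adjusted_mutual_information(partition, reference_labels))
}
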