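#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// CART growing for the bagged binary ensemble.
//
// Trees are stored as parallel arrays in preorder: node 0 is the root,
// children indices are 0-based, -1 marks a leaf.  leaf_value holds the
// positive-class fraction of the bootstrap weight reaching the node (kept at
// internal nodes too), node_cover the bootstrap weight itself.  Splits
// maximize the Gini impurity decrease over `mtry` features sampled per node;
// thresholds are midpoints between consecutive distinct sorted values and
// routing is "left iff x <= threshold".  Ties are broken toward the lowest
// feature index, then the lowest threshold (candidates are scanned in that
// order and only a strict improvement replaces the incumbent).
// ---------------------------------------------------------------------------

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, min_leaf, max_depth; // max_depth < 0 means unlimited

  std::vector<int> cl, cr, feat;
  std::vector<double> thr, val, cover;

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
              int min_leaf_, int max_depth_)
      : X(X_), y(y_), mtry(mtry_), min_leaf(min_leaf_), max_depth(max_depth_) {}

  int new_node() {
    cl.push_back(-1);
    cr.push_back(-1);
    feat.push_back(-1);
    thr.push_back(NA_REAL);
    val.push_back(0.0);
    cover.push_back(0.0);
    return static_cast<int>(cl.size()) - 1;
  }

  static double gini(double pos, double n) {
    double q = pos / n;
    return 2.0 * q * (1.0 - q);
  }

  int build(std::vector<int> &idx, int depth) {
    int node = new_node();
    int n = static_cast<int>(idx.size());
    int pos = 0;
    for (int i : idx) pos += y[i];
    cover[node] = n;
    val[node] = static_cast<double>(pos) / n;

    bool stop_here = (pos == 0 || pos == n) || n < 2 * min_leaf || n < 2 ||
                     (max_depth >= 0 && depth >= max_depth);
    if (stop_here) return node;

    int p = X.ncol();
    int m = std::min(mtry, p);
    // partial Fisher-Yates under the R RNG so runs are seed-reproducible
    std::vector<int> pool(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    for (int j = 0; j < m; ++j) {
      int k = j + static_cast<int>(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(pool[j], pool[k]);
    }
    std::vector<int> cand(pool.begin(), pool.begin() + m);
    std::sort(cand.begin(), cand.end());

    double parent_g = gini(pos, n);
    double best_dec = 0.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<std::pair<double, int> > v(n);
    for (int f : cand) {
      for (int i = 0; i < n; ++i) v[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(v.begin(), v.end());
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += v[i].second;
        if (v[i].first == v[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        int rpos = pos - lpos;
        double dec = parent_g - (static_cast<double>(nl) / n) * gini(lpos, nl) -
                     (static_cast<double>(nr) / n) * gini(rpos, nr);
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = v[i].first / 2.0 + v[i + 1].first / 2.0;
        }
      }
    }
    if (best_f < 0) return node; // no admissible split improves impurity

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    feat[node] = best_f;
    thr[node] = best_thr;
    cl[node] = build(li, depth + 1);
    cr[node] = build(ri, depth + 1);
    return node;
  }
};

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, IntegerVector boot_idx,
                   int mtry, int min_leaf, int max_depth) {
  TreeBuilder tb(X, y, mtry, min_leaf, max_depth);
  std::vector<int> idx(boot_idx.begin(), boot_idx.end());
  tb.build(idx, 0);
  return List::create(
      _["children_left"] = IntegerVector(tb.cl.begin(), tb.cl.end()),
      _["children_right"] = IntegerVector(tb.cr.begin(), tb.cr.end()),
      _["split_feature"] = IntegerVector(tb.feat.begin(), tb.feat.end()),
      _["split_threshold"] = NumericVector(tb.thr.begin(), tb.thr.end()),
      _["leaf_value"] = NumericVector(tb.val.begin(), tb.val.end()),
      _["node_cover"] = NumericVector(tb.cover.begin(), tb.cover.end()));
}

// ---------------------------------------------------------------------------
// Routing
// ---------------------------------------------------------------------------

struct FlatTree {
  IntegerVector cl, cr, feat;
  NumericVector thr, val, cover;
  explicit FlatTree(const List &t)
      : cl(t["children_left"]), cr(t["children_right"]),
        feat(t["split_feature"]), thr(t["split_threshold"]),
        val(t["leaf_value"]), cover(t["node_cover"]) {}
};

// [[Rcpp::export(name = ".predict_trees_cpp")]]
NumericMatrix predict_trees_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    FlatTree tr(trees[t]);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.feat[node] >= 0) {
        node = (X(i, tr.feat[node]) <= tr.thr[node]) ? tr.cl[node] : tr.cr[node];
      }
      out(i, t) = tr.val[node];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Path-dependent tree Shapley values.
//
// Conditional expectations given a feature subset are the cover-weighted
// averages over unconditioned branches; the recursion below keeps, for each
// unique feature on the current path, the fraction of "zero" (feature
// unknown) and "one" (feature known and routed here) paths that reach the
// node, together with the permutation weights needed to read off each
// feature's Shapley contribution at the leaves.
// ---------------------------------------------------------------------------

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *up, int unique_depth, double zero_fraction,
                        double one_fraction, int feature_index) {
  up[unique_depth].feature_index = feature_index;
  up[unique_depth].zero_fraction = zero_fraction;
  up[unique_depth].one_fraction = one_fraction;
  up[unique_depth].pweight = (unique_depth == 0) ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    up[i + 1].pweight += one_fraction * up[i].pweight * (i + 1.0) / (unique_depth + 1.0);
    up[i].pweight = zero_fraction * up[i].pweight * (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(PathElement *up, int unique_depth, int path_index) {
  double one_fraction = up[path_index].one_fraction;
  double zero_fraction = up[path_index].zero_fraction;
  double next_one_portion = up[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      double tmp = up[i].pweight;
      up[i].pweight = next_one_portion * (unique_depth + 1.0) / ((i + 1.0) * one_fraction);
      next_one_portion = tmp - up[i].pweight * zero_fraction * (unique_depth - i) / (unique_depth + 1.0);
    } else {
      up[i].pweight = up[i].pweight * (unique_depth + 1.0) / (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    up[i].feature_index = up[i + 1].feature_index;
    up[i].zero_fraction = up[i + 1].zero_fraction;
    up[i].one_fraction = up[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *up, int unique_depth, int path_index) {
  double one_fraction = up[path_index].one_fraction;
  double zero_fraction = up[path_index].zero_fraction;
  double next_one_portion = up[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      double tmp = next_one_portion * (unique_depth + 1.0) / ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = up[i].pweight - tmp * zero_fraction * (unique_depth - i) / (unique_depth + 1.0);
    } else {
      total += up[i].pweight * (unique_depth + 1.0) / (zero_fraction * (unique_depth - i));
    }
  }
  return total;
}

static void tree_shap_recursive(const FlatTree &tr, const double *x, double *phi,
                                int node, int unique_depth, PathElement *parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *up = parent_path + unique_depth + 1;
  std::copy(parent_path, parent_path + unique_depth, up);
  extend_path(up, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tr.feat[node] < 0) { // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      double w = unwound_path_sum(up, unique_depth, i);
      phi[up[i].feature_index] += w * (up[i].one_fraction - up[i].zero_fraction) * tr.val[node];
    }
    return;
  }

  int f = tr.feat[node];
  int hot = (x[f] <= tr.thr[node]) ? tr.cl[node] : tr.cr[node];
  int cold = (hot == tr.cl[node]) ? tr.cr[node] : tr.cl[node];
  double hot_zero = tr.cover[hot] / tr.cover[node];
  double cold_zero = tr.cover[cold] / tr.cover[node];

  double inc_zero = 1.0, inc_one = 1.0;
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (up[path_index].feature_index == f) break;
  if (path_index != unique_depth + 1) {
    inc_zero = up[path_index].zero_fraction;
    inc_one = up[path_index].one_fraction;
    unwind_path(up, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tr, x, phi, hot, unique_depth + 1, up,
                      hot_zero * inc_zero, inc_one, f);
  tree_shap_recursive(tr, x, phi, cold, unique_depth + 1, up,
                      cold_zero * inc_zero, 0.0, f);
}

static int tree_max_depth(const FlatTree &tr, int node, int depth) {
  if (tr.feat[node] < 0) return depth;
  return std::max(tree_max_depth(tr, tr.cl[node], depth + 1),
                  tree_max_depth(tr, tr.cr[node], depth + 1));
}

// [[Rcpp::export(name = ".tree_shap_cpp")]]
NumericMatrix tree_shap_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericMatrix phi(n, p);
  std::vector<double> xrow(p), phirow(p);
  for (int t = 0; t < T; ++t) {
    FlatTree tr(trees[t]);
    int D = tree_max_depth(tr, 0, 0);
    std::vector<PathElement> buf(((D + 2) * (D + 3)) / 2 + 4);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) { xrow[j] = X(i, j); phirow[j] = 0.0; }
      tree_shap_recursive(tr, xrow.data(), phirow.data(), 0, 0, buf.data(),
                          1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phirow[j];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) /= T;
  return phi;
}
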