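// CART regression trees and exact tree-path SHAP attribution.
// The tree is returned to R as parallel arrays: feature (-1 for leaves),
// threshold, left/right child (0-based, -1 for leaves), value (node mean),
// cover (training weight reaching the node). Split rule: x <= threshold
// goes left; threshold is the midpoint between consecutive distinct values.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

struct BuildNode {
  int feature = -1;
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
  double cover = 0.0;
};

static void build_recursive(const NumericMatrix &X, const NumericVector &y,
                            std::vector<int> &rows, int depth, int max_depth,
                            int min_leaf, int mtry, std::mt19937 &rng,
                            std::vector<BuildNode> &nodes, int node_id) {
  const int n = rows.size();
  double sum = 0.0;
  for (int r : rows) sum += y[r];
  const double mean = sum / n;
  nodes[node_id].value = mean;
  nodes[node_id].cover = n;
  if (depth >= max_depth || n < 2 * min_leaf) return;

  double sse = 0.0;
  for (int r : rows) sse += (y[r] - mean) * (y[r] - mean);
  if (sse <= 1e-12) return;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  if (mtry < p) {
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feats[j], feats[pick(rng)]);
    }
    feats.resize(mtry);
    std::sort(feats.begin(), feats.end());  // deterministic tie order
  }

  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  std::vector<int> ord(rows);
  for (int f : feats) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += y[ord[i]];
      if (X(ord[i + 1], f) <= X(ord[i], f)) continue;  // not a distinct cut
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
      }
    }
  }
  if (best_f < 0) return;

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, best_f) <= best_thr) lrows.push_back(r); else rrows.push_back(r);
  }
  if (lrows.empty() || rrows.empty()) return;

  nodes[node_id].feature = best_f;
  nodes[node_id].threshold = best_thr;
  nodes.push_back(BuildNode());
  nodes[node_id].left = nodes.size() - 1;
  nodes.push_back(BuildNode());
  nodes[node_id].right = nodes.size() - 1;
  build_recursive(X, y, lrows, depth + 1, max_depth, min_leaf, mtry, rng,
                  nodes, nodes[node_id].left);
  build_recursive(X, y, rrows, depth + 1, max_depth, min_leaf, mtry, rng,
                  nodes, nodes[node_id].right);
}

// [[Rcpp::export]]
List cs_tree_fit(NumericMatrix X, NumericVector y, IntegerVector row_idx,
                 int max_depth, int min_leaf, int mtry, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> rows(row_idx.begin(), row_idx.end());
  std::vector<BuildNode> nodes(1);
  build_recursive(X, y, rows, 0, max_depth, min_leaf,
                  std::min(std::max(mtry, 1), (int)X.ncol()), rng, nodes, 0);
  const int m = nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m), cover(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
    cover[i] = nodes[i].cover;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["cover"] = cover);
}

// [[Rcpp::export]]
NumericVector cs_tree_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    out[i] = value[node];
  }
  return out;
}

// ---- TreeSHAP (path-dependent feature perturbation), Lundberg et al. ----

struct PathElement {
  int feature_index;
  double zero_fraction, one_fraction, pweight;
};

static void extend_path(std::vector<PathElement> &path, unsigned depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path.push_back({feature_index, zero_fraction, one_fraction,
                  depth == 0 ? 1.0 : 0.0});
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight +=
        one_fraction * path[i].pweight * (i + 1) / (double)(depth + 1);
    path[i].pweight =
        zero_fraction * path[i].pweight * (depth - i) / (double)(depth + 1);
  }
}

static void unwind_path(std::vector<PathElement> &path, unsigned depth,
                        unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one * (depth + 1) / ((i + 1) * one_fraction);
      next_one = tmp - path[i].pweight * zero_fraction * (depth - i) /
                           (double)(depth + 1);
    } else {
      path[i].pweight =
          path[i].pweight * (depth + 1) / (zero_fraction * (depth - i));
    }
  }
  for (unsigned i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
  path.pop_back();
}

static double unwound_path_sum(const std::vector<PathElement> &path,
                               unsigned depth, unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one = path[depth].pweight, total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one * (depth + 1) / ((i + 1) * one_fraction);
      total += tmp;
      next_one = path[i].pweight -
                 tmp * zero_fraction * ((depth - i) / (double)(depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((depth - i) / (double)(depth + 1));
    }
  }
  return total;
}

struct TreeArrays {
  const int *feature, *left, *right;
  const double *threshold, *value, *cover;
};

static void shap_recurse(const TreeArrays &t, const double *x, double *phi,
                         int node, std::vector<PathElement> path,
                         unsigned depth, double parent_zero,
                         double parent_one, int parent_feature) {
  extend_path(path, depth, parent_zero, parent_one, parent_feature);
  if (t.feature[node] < 0) {  // leaf
    for (unsigned i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * t.value[node];
    }
    return;
  }
  const int f = t.feature[node];
  const int hot = (x[f] <= t.threshold[node]) ? t.left[node] : t.right[node];
  const int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  const double hot_zero = t.cover[hot] / t.cover[node];
  const double cold_zero = t.cover[cold] / t.cover[node];
  double incoming_zero = 1.0, incoming_one = 1.0;
  unsigned k = 0;
  for (k = 1; k <= depth; ++k)
    if (path[k].feature_index == f) break;
  if (k <= depth) {
    incoming_zero = path[k].zero_fraction;
    incoming_one = path[k].one_fraction;
    unwind_path(path, depth, k);
    depth -= 1;
  }
  shap_recurse(t, x, phi, hot, path, depth + 1, hot_zero * incoming_zero,
               incoming_one, f);
  shap_recurse(t, x, phi, cold, path, depth + 1, cold_zero * incoming_zero,
               0.0, f);
}

// Returns an n x (p + 1) matrix: per-feature SHAP values plus the expected
// value (base rate) in the last column; rowSums equal the tree prediction.
// [[Rcpp::export]]
NumericMatrix cs_tree_shap(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"],
                cover = tree["cover"];
  TreeArrays t{feature.begin(), left.begin(), right.begin(),
               threshold.begin(), value.begin(), cover.begin()};
  const int n = X.nrow(), p = X.ncol(), m = feature.size();
  double base = 0.0;
  for (int i = 0; i < m; ++i)
    if (feature[i] < 0) base += value[i] * cover[i];
  base /= cover[0];
  NumericMatrix out(n, p + 1);
  std::vector<double> xrow(p), phi(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    std::vector<PathElement> path;
    path.reserve(64);
    shap_recurse(t, xrow.data(), phi.data(), 0, path, 0, 1.0, 1.0, -1);
    for (int j = 0; j < p; ++j) out(i, j) = phi[j];
    out(i, p) = base;
  }
  return out;
}
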