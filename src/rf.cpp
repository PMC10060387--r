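// Random-forest regressor: bagged CART trees with exhaustive
// squared-error split search. Small by design (few features, shallow
// trees) and deterministic given a seed: each tree draws its bootstrap
// sample from its own mt19937 stream, independent of R's RNG.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;      // -1 for a leaf
  double threshold;
  int left, right;  // 0-based node indices, -1 for none
  double value;     // mean response of node samples
  int n;            // node sample count
};

struct SplitResult {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double score = 0.0;  // SSE reduction
};

static SplitResult best_split(const NumericMatrix& X,
                              const NumericVector& y,
                              const std::vector<int>& idx,
                              int min_samples_leaf) {
  SplitResult best;
  const int n = (int)idx.size();
  const int p = X.ncol();
  double sum_all = 0.0;
  for (int i : idx) sum_all += y[i];

  std::vector<double> xv(n);
  for (int f = 0; f < p; ++f) {
    for (int k = 0; k < n; ++k) xv[k] = X(idx[k], f);
    std::vector<int> perm(n);
    for (int k = 0; k < n; ++k) perm[k] = k;
    std::stable_sort(perm.begin(), perm.end(),
                     [&](int a, int b) { return xv[a] < xv[b]; });
    // prefix scan: split between consecutive distinct feature values
    double sum_left = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      int i = idx[perm[k]];
      sum_left += y[i];
      double xa = xv[perm[k]], xb = xv[perm[k + 1]];
      if (xa == xb) continue;
      int nl = k + 1, nr = n - nl;
      if (nl < min_samples_leaf || nr < min_samples_leaf) continue;
      double sum_right = sum_all - sum_left;
      // SSE reduction up to constants: sum_l^2/n_l + sum_r^2/n_r
      double score = sum_left * sum_left / nl + sum_right * sum_right / nr;
      if (!best.found || score > best.score) {
        best.found = true;
        best.feature = f;
        best.threshold = 0.5 * (xa + xb);
        best.score = score;
      }
    }
  }
  return best;
}

static int grow(const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int depth, int max_depth,
                int min_samples_split, int min_samples_leaf,
                std::vector<Node>& nodes) {
  Node node;
  const int n = (int)idx.size();
  double s = 0.0;
  for (int i : idx) s += y[i];
  node.value = s / n;
  node.n = n;
  node.feature = -1;
  node.threshold = 0.0;
  node.left = node.right = -1;
  int me = (int)nodes.size();
  nodes.push_back(node);

  if (depth >= max_depth || n < min_samples_split) return me;
  SplitResult sp = best_split(X, y, idx, min_samples_leaf);
  if (!sp.found) return me;
  // no-gain splits are skipped (pure node)
  double sse_parent = s * s / n;
  if (sp.score - sse_parent <= 1e-12 * (1.0 + std::abs(sse_parent)))
    return me;

  std::vector<int> left_idx, right_idx;
  for (int i : idx) {
    if (X(i, sp.feature) <= sp.threshold) left_idx.push_back(i);
    else right_idx.push_back(i);
  }
  if (left_idx.empty() || right_idx.empty()) return me;
  nodes[me].feature = sp.feature;
  nodes[me].threshold = sp.threshold;
  int l = grow(X, y, left_idx, depth + 1, max_depth, min_samples_split,
               min_samples_leaf, nodes);
  int r = grow(X, y, right_idx, depth + 1, max_depth, min_samples_split,
               min_samples_leaf, nodes);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_estimators,
                int max_depth, int min_samples_split, int min_samples_leaf,
                int seed, bool bootstrap) {
  const int n = X.nrow();
  List trees(n_estimators);
  for (int t = 0; t < n_estimators; ++t) {
    std::mt19937 rng((unsigned)seed + 0x9e3779b9u * (unsigned)(t + 1));
    std::vector<int> idx(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> pick(0, n - 1);
      for (int i = 0; i < n; ++i) idx[i] = pick(rng);
      std::sort(idx.begin(), idx.end());
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    std::vector<Node> nodes;
    grow(X, y, idx, 0, max_depth, min_samples_split, min_samples_leaf,
         nodes);
    const int m = (int)nodes.size();
    NumericMatrix tm(m, 5);
    for (int i = 0; i < m; ++i) {
      tm(i, 0) = nodes[i].feature;  // -1 leaf, else 0-based feature
      tm(i, 1) = nodes[i].threshold;
      tm(i, 2) = nodes[i].left;
      tm(i, 3) = nodes[i].right;
      tm(i, 4) = nodes[i].value;
    }
    trees[t] = tm;
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)tm(node, 0) >= 0) {
        int f = (int)tm(node, 0);
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2)
                                        : (int)tm(node, 3);
      }
      out[i] += tm(node, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
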