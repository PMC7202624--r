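#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// CART-style classification trees with per-node random feature subsetting
// (Gini impurity, midpoint thresholds, grown to purity by default),
// bagged into a forest. Randomness comes from R's RNG stream so results
// are reproducible under set.seed().

struct TreeBuilder {
  const NumericMatrix &X; // n x d
  const IntegerVector &y; // 0/1
  int mtry, min_node, max_depth;
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> prob;     // P(class 1) at node

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
              int min_node_, int max_depth_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_) {}

  int new_node(double p) {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    prob.push_back(p);
    return (int)feature.size() - 1;
  }

  // sample mtry distinct feature indices from 0..d-1 via R RNG
  void sample_features(int d, std::vector<int> &out) {
    out.clear();
    std::vector<int> pool(d);
    for (int k = 0; k < d; ++k) pool[k] = k;
    int m = std::min(mtry, d);
    for (int k = 0; k < m; ++k) {
      int r = k + (int)(unif_rand() * (d - k));
      if (r >= d) r = d - 1;
      std::swap(pool[k], pool[r]);
      out.push_back(pool[k]);
    }
  }

  int build(std::vector<int> &idx, int lo, int hi, int depth) {
    int n = hi - lo;
    int n1 = 0;
    for (int t = lo; t < hi; ++t) n1 += y[idx[t]];
    double p = (double)n1 / n;
    if (n1 == 0 || n1 == n || n < 2 * min_node || depth >= max_depth)
      return new_node(p);

    std::vector<int> feats;
    sample_features(X.ncol(), feats);
    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    double parent_gini = 2.0 * p * (1.0 - p) * n;
    std::vector<std::pair<double, int> > vals(n);
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      int f = feats[fi];
      for (int t = 0; t < n; ++t)
        vals[t] = std::make_pair(X(idx[lo + t], f), y[idx[lo + t]]);
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int t = 0; t < n - 1; ++t) {
        l1 += vals[t].second;
        if (vals[t].first == vals[t + 1].first) continue;
        int nl = t + 1, nr_ = n - nl;
        int r1 = n1 - l1;
        double gl = 2.0 * (double)l1 * (nl - l1) / nl;
        double gr = 2.0 * (double)r1 * (nr_ - r1) / nr_;
        double gain = parent_gini - gl - gr;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (best_f < 0) return new_node(p);
    // partition idx[lo,hi) in place
    int mid = lo;
    for (int t = lo; t < hi; ++t)
      if (X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
    if (mid == lo || mid == hi) return new_node(p);
    int node = new_node(p);
    feature[node] = best_f;
    threshold[node] = best_thr;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid, hi, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, int max_depth) {
  int n = X.nrow();
  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[t] = r;
    }
    TreeBuilder tb(X, y, mtry, min_node, max_depth);
    tb.build(idx, 0, n, 0);
    trees[b] = List::create(
        _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
        _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
        _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
        _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
        _["prob"] = NumericVector(tb.prob.begin(), tb.prob.end()));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int b = 0; b < nt; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      out[i] += prob[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
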