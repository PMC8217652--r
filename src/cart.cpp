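// Greedy binary CART for two-class problems (Gini impurity), the base
// learner for the random forest and bagging classifiers. Feature
// subsampling uses R's RNG so results are reproducible via set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> prob;      // P(class 1) at node
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

// sample `m` distinct feature indices out of p (partial Fisher-Yates)
void sample_features(std::vector<int>& feats, int p, int m) {
  feats.resize(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }
  feats.resize(m);
}

int grow(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& rows, int lo, int hi, int depth,
         int mtry, int max_depth, int min_split) {
  int n = hi - lo;
  double n1 = 0.0;
  for (int i = lo; i < hi; ++i) n1 += y[rows[i]];
  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.prob.push_back(n1 / n);

  double g0 = gini(n1, n);
  if (n < min_split || depth >= max_depth || n1 == 0.0 || n1 == (double)n)
    return node;

  std::vector<int> feats;
  sample_features(feats, X.ncol(), mtry);

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, int> > vals(n);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) {
      int r = rows[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    double l1 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      double nl = i + 1, nr = n - nl;
      double gain = g0 - (nl / n) * gini(l1, nl) - (nr / n) * gini(n1 - l1, nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition rows[lo..hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_f) <= best_thr) std::swap(rows[i], rows[mid++]);
  if (mid == lo || mid == hi) return node;  // numeric safety

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int l = grow(tree, X, y, rows, lo, mid, depth + 1, mtry, max_depth, min_split);
  int r = grow(tree, X, y, rows, mid, hi, depth + 1, mtry, max_depth, min_split);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cart_fit(NumericMatrix X, IntegerVector y, IntegerVector rows,
              int mtry, int max_depth, int min_split) {
  std::vector<int> rw(rows.size());
  for (int i = 0; i < rows.size(); ++i) rw[i] = rows[i] - 1;  // 1- to 0-based
  Tree tree;
  grow(tree, X, y, rw, 0, (int)rw.size(), 0, mtry, max_depth, min_split);
  return List::create(_["feature"] = wrap(tree.feature),
                      _["threshold"] = wrap(tree.threshold),
                      _["left"] = wrap(tree.left),
                      _["right"] = wrap(tree.right),
                      _["prob"] = wrap(tree.prob));
}

// [[Rcpp::export]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector prob = tree["prob"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = prob[node];
  }
  return out;
}
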