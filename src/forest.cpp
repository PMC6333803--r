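// Bagged CART regression forest. No tree-ensemble package ships with this
// toolchain, so the ensemble behind the arbitrage feature-ranking stage is
// implemented here: bootstrap-resampled depth-limited variance-reduction
// trees with per-node feature subsampling (mtry), mean-aggregated.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  // flat arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(NA_REAL);
    return (int)feature.size() - 1;
  }
};

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

// Best variance-reduction split over a random subset of features.
Split best_split(const NumericMatrix& X, const NumericVector& y,
                 const std::vector<int>& idx, int mtry, int min_bucket,
                 std::mt19937& gen) {
  const int p = X.ncol();
  const int n = (int)idx.size();

  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::shuffle(feats.begin(), feats.end(), gen);

  double sum_all = 0.0;
  for (int i : idx) sum_all += y[i];

  Split best;
  std::vector<std::pair<double, double>> xy(n);
  int tried = 0;
  for (int f = 0; f < p && tried < mtry; ++f) {
    const int j = feats[f];
    for (int k = 0; k < n; ++k) xy[k] = {X(idx[k], j), y[idx[k]]};
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;  // constant in node
    ++tried;

    double sum_left = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      sum_left += xy[k].second;
      if (xy[k].first == xy[k + 1].first) continue;  // only between distinct x
      const int nl = k + 1, nr = n - nl;
      if (nl < min_bucket || nr < min_bucket) continue;
      const double sum_right = sum_all - sum_left;
      // SSE reduction up to a constant: max of sum^2/n terms
      const double gain =
          sum_left * sum_left / nl + sum_right * sum_right / nr -
          sum_all * sum_all / n;
      if (gain > best.gain + 1e-12) {
        best.feature = j;
        best.threshold = 0.5 * (xy[k].first + xy[k + 1].first);
        best.gain = gain;
      }
    }
  }
  return best;
}

void grow(Tree& tree, int node, const NumericMatrix& X, const NumericVector& y,
          std::vector<int>& idx, int depth, int max_depth, int min_split,
          int min_bucket, int mtry, std::mt19937& gen) {
  const int n = (int)idx.size();
  double mean = 0.0;
  for (int i : idx) mean += y[i];
  mean /= n;
  tree.value[node] = mean;

  if (depth >= max_depth || n < min_split) return;
  Split s = best_split(X, y, idx, mtry, min_bucket, gen);
  if (s.feature < 0) return;

  std::vector<int> li, ri;
  li.reserve(n);
  ri.reserve(n);
  for (int i : idx) {
    if (X(i, s.feature) <= s.threshold) li.push_back(i); else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return;

  tree.feature[node] = s.feature;
  tree.threshold[node] = s.threshold;
  const int l = tree.new_node();
  const int r = tree.new_node();
  tree.left[node] = l;
  tree.right[node] = r;
  grow(tree, l, X, y, li, depth + 1, max_depth, min_split, min_bucket, mtry, gen);
  grow(tree, r, X, y, ri, depth + 1, max_depth, min_split, min_bucket, mtry, gen);
}

double predict_one(const List& tr, const NumericMatrix& X, int row) {
  const IntegerVector feature = tr["feature"];
  const NumericVector threshold = tr["threshold"];
  const IntegerVector left = tr["left"];
  const IntegerVector right = tr["right"];
  const NumericVector value = tr["value"];
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return value[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int max_depth, int min_split, int min_bucket, int seed) {
  const int n = X.nrow();
  std::mt19937 gen((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(gen);
    Tree tree;
    const int root = tree.new_node();
    grow(tree, root, X, y, idx, 0, max_depth, min_split, min_bucket, mtry, gen);
    trees[t] = List::create(
        _["feature"] = wrap(tree.feature), _["threshold"] = wrap(tree.threshold),
        _["left"] = wrap(tree.left), _["right"] = wrap(tree.right),
        _["value"] = wrap(tree.value));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
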