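// Entropy-criterion CART classifier for wide flattened-image features.
// Greedy binary splits maximizing information gain; grown depth-first.
// (Formula-based tree fitters need O(p^2) terms bookkeeping, which is
// infeasible at ~50k features; this works directly on the matrix.)

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;     // -1 => leaf
  double threshold = 0; // go left if x <= threshold
  int left = -1, right = -1;
  int pred = 0;
  double purity = 0;
};

static double entropy_of(const std::vector<int>& counts, int total) {
  if (total == 0) return 0.0;
  double h = 0.0;
  for (int c : counts) {
    if (c > 0) {
      double p = (double)c / total;
      h -= p * std::log(p);
    }
  }
  return h;
}

static int majority(const std::vector<int>& counts) {
  return (int)(std::max_element(counts.begin(), counts.end()) - counts.begin());
}

static void grow(const NumericMatrix& x, const IntegerVector& y, int k,
                 std::vector<int>& idx, int depth, int max_depth,
                 int min_split, std::vector<Node>& nodes, int me) {
  const int n = (int)idx.size();
  std::vector<int> counts(k, 0);
  for (int i : idx) counts[y[i]]++;
  nodes[me].pred = majority(counts);
  nodes[me].purity = (double)counts[nodes[me].pred] / n;
  const double h_parent = entropy_of(counts, n);
  if (depth >= max_depth || n < min_split || h_parent <= 0.0) return;

  const int p = x.ncol();
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  std::vector<int> lc(k), rc(k);
  for (int j = 0; j < p; ++j) {
    for (int t = 0; t < n; ++t) vals[t] = {x(idx[t], j), y[idx[t]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::fill(lc.begin(), lc.end(), 0);
    rc = counts;
    for (int t = 0; t < n - 1; ++t) {
      lc[vals[t].second]++;
      rc[vals[t].second]--;
      if (vals[t].first == vals[t + 1].first) continue;
      const double h = ((t + 1) * entropy_of(lc, t + 1) +
                        (n - t - 1) * entropy_of(rc, n - t - 1)) / n;
      const double gain = h_parent - h;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = j;
        best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  std::vector<int> li, ri;
  for (int i : idx) {
    if (x(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return;
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  nodes[me].left = (int)nodes.size();
  nodes.emplace_back();
  grow(x, y, k, li, depth + 1, max_depth, min_split, nodes, nodes[me].left);
  nodes[me].right = (int)nodes.size();
  nodes.emplace_back();
  grow(x, y, k, ri, depth + 1, max_depth, min_split, nodes, nodes[me].right);
}

// [[Rcpp::export]]
List entropy_tree_fit_cpp(NumericMatrix x, IntegerVector y, int n_classes,
                          int max_depth, int min_split) {
  std::vector<Node> nodes;
  nodes.emplace_back();
  std::vector<int> idx(x.nrow());
  for (int i = 0; i < x.nrow(); ++i) idx[i] = i;
  grow(x, y, n_classes, idx, 0, max_depth, min_split, nodes, 0);
  const int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m), pred(m);
  NumericVector threshold(m), purity(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
    purity[i] = nodes[i].purity;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["pred"] = pred, _["purity"] = purity);
}

// [[Rcpp::export]]
IntegerVector entropy_tree_predict_cpp(List tree, NumericMatrix x) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"], pred = tree["pred"];
  IntegerVector out(x.nrow());
  for (int i = 0; i < x.nrow(); ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (x(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
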