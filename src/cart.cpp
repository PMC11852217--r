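#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Greedy CART regression tree with weighted variance-reduction splits.
// Thresholds are midpoints of sorted distinct feature values; ties between
// candidate splits are broken toward the first feature in scan order and the
// smallest threshold, so fits are deterministic given feature order. Per-split
// feature subsampling (mtry < p) draws from R's RNG; when mtry == p no RNG is
// consumed at all, which makes the subsampling-free paths bit-identical to a
// plain tree.

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;     // weighted mean of node targets
};

static int grow_node(const NumericMatrix& X, const NumericVector& y,
                     const NumericVector& w, std::vector<int>& idx, int depth,
                     int max_depth, int min_leaf, int mtry, TreeBuf& tb) {
  const int node = (int)tb.feature.size();
  tb.feature.push_back(-1);
  tb.threshold.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);

  double sw = 0.0, swy = 0.0, swyy = 0.0;
  for (int i : idx) {
    sw += w[i];
    swy += w[i] * y[i];
    swyy += w[i] * y[i] * y[i];
  }
  tb.value.push_back(swy / sw);

  const int n = (int)idx.size();
  if (depth >= max_depth || n < 2 * min_leaf) return node;
  const double sse = swyy - swy * swy / sw;
  if (sse <= 1e-12) return node; // constant target: leaf

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  if (mtry < p) {
    // partial Fisher-Yates using R's RNG; sorted afterwards for a
    // deterministic scan order given the drawn set
    for (int j = 0; j < mtry; ++j) {
      int k = j + (int)std::floor(unif_rand() * (double)(p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }
    feats.resize(mtry);
    std::sort(feats.begin(), feats.end());
  }

  int best_f = -1, best_cut = -1;
  double best_thr = 0.0, best_dec = 1e-12;
  std::vector<std::pair<double, int> > vals(n);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    const int f = feats[fi];
    for (int a = 0; a < n; ++a) vals[a] = std::make_pair(X(idx[a], f), idx[a]);
    std::sort(vals.begin(), vals.end());
    double lsw = 0.0, lswy = 0.0, lswyy = 0.0;
    for (int a = 0; a < n - 1; ++a) {
      const int i = vals[a].second;
      lsw += w[i];
      lswy += w[i] * y[i];
      lswyy += w[i] * y[i] * y[i];
      if (vals[a + 1].first <= vals[a].first) continue; // tied values
      if (a + 1 < min_leaf || n - a - 1 < min_leaf) continue;
      const double rsw = sw - lsw, rswy = swy - lswy, rswyy = swyy - lswyy;
      if (lsw <= 0.0 || rsw <= 0.0) continue;
      const double child =
          (lswyy - lswy * lswy / lsw) + (rswyy - rswy * rswy / rsw);
      const double dec = sse - child;
      if (dec > best_dec * (1.0 + 1e-12) && dec > best_dec) {
        best_dec = dec;
        best_f = f;
        best_cut = a;
        best_thr = 0.5 * (vals[a].first + vals[a + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  std::vector<int> li, ri;
  li.reserve(best_cut + 1);
  ri.reserve(n - best_cut - 1);
  for (int i : idx) {
    if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
  }
  tb.feature[node] = best_f;
  tb.threshold[node] = best_thr;
  tb.left[node] = grow_node(X, y, w, li, depth + 1, max_depth, min_leaf, mtry, tb);
  tb.right[node] = grow_node(X, y, w, ri, depth + 1, max_depth, min_leaf, mtry, tb);
  return node;
}

// [[Rcpp::export]]
List cart_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth, int min_leaf, int mtry) {
  const int n = X.nrow();
  if (y.size() != n || w.size() != n) stop("dimension mismatch");
  if (min_leaf < 1) stop("min_leaf must be >= 1");
  if (mtry < 1) mtry = 1;
  if (mtry > X.ncol()) mtry = X.ncol();
  TreeBuf tb;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  grow_node(X, y, w, idx, 0, max_depth, min_leaf, mtry, tb);
  return List::create(_["feature"] = wrap(tb.feature),
                      _["threshold"] = wrap(tb.threshold),
                      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
                      _["value"] = wrap(tb.value));
}

// [[Rcpp::export]]
NumericVector cart_predict_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
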