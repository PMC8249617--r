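#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
using namespace Rcpp;

// Bagged CART classification forest: exhaustive Gini split search over a
// random subset of mtry features per node, bootstrap resampling per tree,
// out-of-bag majority votes for a training-set accuracy estimate.
// Deterministic for a given seed (own mt19937_64, no R RNG involvement).

struct TreeVecs {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right, pred;
};

static int grow(const NumericMatrix& X, const IntegerVector& y, int K,
                std::vector<int>& idx, int lo, int hi, int depth,
                int max_depth, int min_node, int mtry, std::mt19937_64& rng,
                TreeVecs& T, std::vector<int>& featbuf) {
  int node = T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back(0);

  int n = hi - lo;
  std::vector<int> cnt(K, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int maj = 0;
  for (int k = 1; k < K; ++k)
    if (cnt[k] > cnt[maj]) maj = k;
  T.pred[node] = maj;

  bool pure = cnt[maj] == n;
  if (pure || n < 2 * min_node || n < 2 ||
      (max_depth > 0 && depth >= max_depth))
    return node;

  // parent Gini (times n)
  double parent = (double)n;
  for (int k = 0; k < K; ++k) parent -= (double)cnt[k] * cnt[k] / n;

  int p = X.ncol();
  for (int i = 0; i < p; ++i) featbuf[i] = i;
  // partial Fisher-Yates for mtry candidate features
  int m = std::min(mtry, p);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(rng() % (p - i));
    std::swap(featbuf[i], featbuf[j]);
  }

  double best_gain = 1e-12;
  int best_f = -1, best_pos = -1;
  double best_thr = 0.0;
  std::vector<int> order(n), lcnt(K), rcnt(K);
  std::vector<double> vals(n);

  for (int fi = 0; fi < m; ++fi) {
    int f = featbuf[fi];
    for (int i = 0; i < n; ++i) {
      order[i] = idx[lo + i];
      vals[i] = X(order[i], f);
    }
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    std::stable_sort(perm.begin(), perm.end(),
                     [&](int a, int b) { return vals[a] < vals[b]; });
    std::fill(lcnt.begin(), lcnt.end(), 0);
    for (int k = 0; k < K; ++k) rcnt[k] = cnt[k];
    for (int i = 0; i < n - 1; ++i) {
      int c = y[order[perm[i]]];
      lcnt[c]++; rcnt[c]--;
      double vlo = vals[perm[i]], vhi = vals[perm[i + 1]];
      if (vlo >= vhi) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double gl = (double)nl, gr = (double)nr;
      for (int k = 0; k < K; ++k) {
        gl -= (double)lcnt[k] * lcnt[k] / nl;
        gr -= (double)rcnt[k] * rcnt[k] / nr;
      }
      double gain = parent - gl - gr;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_pos = i;
        best_thr = 0.5 * (vlo + vhi);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo, hi) by the chosen split, stable
  std::vector<int> lpart, rpart;
  lpart.reserve(n); rpart.reserve(n);
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) lpart.push_back(idx[i]);
    else rpart.push_back(idx[i]);
  }
  for (size_t i = 0; i < lpart.size(); ++i) idx[lo + i] = lpart[i];
  for (size_t i = 0; i < rpart.size(); ++i) idx[lo + lpart.size() + i] = rpart[i];
  int mid = lo + lpart.size();

  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  T.left[node] = grow(X, y, K, idx, lo, mid, depth + 1, max_depth, min_node,
                      mtry, rng, T, featbuf);
  T.right[node] = grow(X, y, K, idx, mid, hi, depth + 1, max_depth, min_node,
                       mtry, rng, T, featbuf);
  return node;
}

static int tree_predict_one(const List& tree, const NumericMatrix& X, int row) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"], pred = tree["pred"];
  int node = 0;
  while (feature[node] >= 0)
    node = X(row, feature[node]) <= threshold[node] ? left[node] : right[node];
  return pred[node];
}

// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int K, int n_trees,
                  int mtry, int max_depth, int min_node, int seed) {
  int n = X.nrow();
  std::mt19937_64 rng((uint64_t)seed * 2654435761ull + 1ull);
  List trees(n_trees);
  IntegerMatrix oob_votes(n, K);
  std::vector<int> featbuf(X.ncol());
  for (int t = 0; t < n_trees; ++t) {
    std::vector<char> inbag(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(rng() % n);
      idx[i] = j;
      inbag[j] = 1;
    }
    TreeVecs T;
    grow(X, y, K, idx, 0, n, 0, max_depth, min_node, mtry, rng, T, featbuf);
    List tr = List::create(_["feature"] = IntegerVector(T.feature.begin(), T.feature.end()),
                           _["threshold"] = NumericVector(T.threshold.begin(), T.threshold.end()),
                           _["left"] = IntegerVector(T.left.begin(), T.left.end()),
                           _["right"] = IntegerVector(T.right.begin(), T.right.end()),
                           _["pred"] = IntegerVector(T.pred.begin(), T.pred.end()));
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_votes(i, tree_predict_one(tr, X, i))++;
    trees[t] = tr;
  }
  return List::create(_["trees"] = trees, _["oob_votes"] = oob_votes);
}

// [[Rcpp::export]]
IntegerMatrix cpp_rf_votes(List trees, NumericMatrix X, int K) {
  int n = X.nrow(), nt = trees.size();
  IntegerMatrix votes(n, K);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      votes(i, pred[node])++;
    }
  }
  return votes;
}
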