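#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimal CART forest (gini, bootstrap, per-split feature sampling).
// Trees are flat tables: columns feat, thr, left, right, pred.
// feat == -1 marks a leaf. Uses R's RNG so results follow set.seed().

struct TreeBuf {
  std::vector<double> feat, thr, left, right, pred;
};

static int majority_class(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = (int)k;
  return best;
}

static int build_node(const NumericMatrix &X, const IntegerVector &y, int K,
                      std::vector<int> &idx, int lo, int hi, int depth,
                      int maxdepth, int minnode, int mtry, TreeBuf &T) {
  int n = hi - lo, d = X.ncol();
  std::vector<int> cnt(K, 0);
  for (int a = lo; a < hi; ++a) cnt[y[idx[a]]]++;
  int maj = majority_class(cnt);
  bool pure = cnt[maj] == n;
  int me = (int)T.feat.size();
  T.feat.push_back(-1); T.thr.push_back(0); T.left.push_back(-1);
  T.right.push_back(-1); T.pred.push_back(maj);
  if (pure || depth >= maxdepth || n < 2 * minnode) return me;

  // sample mtry distinct features (partial Fisher-Yates via R RNG)
  std::vector<int> feats(d);
  for (int j = 0; j < d; ++j) feats[j] = j;
  int m = std::min(mtry, d);
  for (int j = 0; j < m; ++j) {
    int pick = j + (int)std::floor(unif_rand() * (d - j));
    if (pick >= d) pick = d - 1;
    std::swap(feats[j], feats[pick]);
  }

  double base_gini = 1.0;
  for (int k = 0; k < K; ++k)
    base_gini -= ((double)cnt[k] / n) * ((double)cnt[k] / n);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_t = 0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    std::vector<int> lc(K, 0);
    std::vector<int> rc(cnt);
    for (int a = 0; a < n - 1; ++a) {
      int c = y[ord[a]];
      lc[c]++; rc[c]--;
      double xa = X(ord[a], f), xb = X(ord[a + 1], f);
      if (xb <= xa) continue;
      int nl = a + 1, nr = n - nl;
      if (nl < minnode || nr < minnode) continue;
      double gl = 1.0, gr = 1.0;
      for (int k = 0; k < K; ++k) {
        gl -= ((double)lc[k] / nl) * ((double)lc[k] / nl);
        gr -= ((double)rc[k] / nr) * ((double)rc[k] / nr);
      }
      double gain = base_gini - ((double)nl / n) * gl - ((double)nr / n) * gr;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_t = 0.5 * (xa + xb);
      }
    }
  }
  if (best_f < 0) return me;
  // partition idx[lo, hi) by the split
  std::vector<int> L, R;
  for (int a = lo; a < hi; ++a) {
    if (X(idx[a], best_f) <= best_t) L.push_back(idx[a]);
    else R.push_back(idx[a]);
  }
  for (size_t a = 0; a < L.size(); ++a) idx[lo + a] = L[a];
  for (size_t a = 0; a < R.size(); ++a) idx[lo + L.size() + a] = R[a];
  T.feat[me] = best_f;
  T.thr[me] = best_t;
  int lchild = build_node(X, y, K, idx, lo, lo + (int)L.size(), depth + 1,
                          maxdepth, minnode, mtry, T);
  T.left[me] = lchild;
  int rchild = build_node(X, y, K, idx, lo + (int)L.size(), hi, depth + 1,
                          maxdepth, minnode, mtry, T);
  T.right[me] = rchild;
  return me;
}

// [[Rcpp::export]]
List forest_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                    int mtry, int maxdepth, int minnode) {
  int n = X.nrow();
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int a = 0; a < n; ++a) {
      int pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[a] = pick;
    }
    TreeBuf T;
    build_node(X, y, nclass, idx, 0, n, 0, maxdepth, minnode, mtry, T);
    int m = (int)T.feat.size();
    NumericMatrix tab(m, 5);
    for (int a = 0; a < m; ++a) {
      tab(a, 0) = T.feat[a]; tab(a, 1) = T.thr[a]; tab(a, 2) = T.left[a];
      tab(a, 3) = T.right[a]; tab(a, 4) = T.pred[a];
    }
    forest[t] = tab;
  }
  return forest;
}

// Per-class tree votes for each row of X (n x nclass counts).
// [[Rcpp::export]]
IntegerMatrix forest_votes_cpp(List forest, NumericMatrix X, int nclass) {
  int n = X.nrow();
  IntegerMatrix votes(n, nclass);
  std::fill(votes.begin(), votes.end(), 0);
  for (int t = 0; t < forest.size(); ++t) {
    NumericMatrix tab = forest[t];
    for (int a = 0; a < n; ++a) {
      int node = 0;
      while (tab(node, 0) >= 0) {
        int f = (int)tab(node, 0);
        node = X(a, f) <= tab(node, 1) ? (int)tab(node, 2) : (int)tab(node, 3);
      }
      votes(a, (int)tab(node, 4))++;
    }
  }
  return votes;
}
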