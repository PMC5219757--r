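#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// A compact random forest for binary classification: bootstrap-bagged CART
// trees with Gini impurity and per-node random feature subsampling (mtry).
// Written here because no tree/forest package is available in the target
// environment.  Randomness comes from R's RNG, so fits are reproducible
// under set.seed().

namespace {

struct Tree {
  std::vector<int> var;       // split feature, -1 for leaf
  std::vector<double> thr;    // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<int> pred;      // leaf class (0/1)
};

int add_node(Tree &t) {
  t.var.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(0);
  return (int) t.var.size() - 1;
}

double gini(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0) return 0.0;
  double p0 = c0 / n, p1 = c1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

// sample 'take' feature indices without replacement from 0..p-1
void sample_features(int p, int take, std::vector<int> &pool,
                     std::vector<int> &out) {
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < take; ++i) {
    int j = i + (int) (unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

void grow(Tree &t, int node, const NumericMatrix &X, const IntegerVector &y,
          std::vector<int> &idx, int lo, int hi, int depth, int max_depth,
          int mtry, std::vector<int> &pool, std::vector<int> &feats,
          std::vector< std::pair<double, int> > &buf) {
  int n = hi - lo;
  int c1 = 0;
  for (int i = lo; i < hi; ++i) c1 += y[idx[i]];
  int c0 = n - c1;
  t.pred[node] = (c1 > c0) ? 1 : 0;
  if (n < 2 || c0 == 0 || c1 == 0 || depth >= max_depth) return;

  const int p = X.ncol();
  sample_features(p, std::min(mtry, p), pool, feats);

  double parent_imp = gini(c0, c1);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    buf.resize(n);
    for (int i = 0; i < n; ++i)
      buf[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) continue;
    double l0 = 0, l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      if (buf[i].second) l1++; else l0++;
      if (buf[i].first == buf[i + 1].first) continue;
      double nl = l0 + l1, nr = n - nl;
      double imp = (nl * gini(l0, l1) + nr * gini(c0 - l0, c1 - l1)) / n;
      double gain = parent_imp - imp;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;

  t.var[node] = best_f;
  t.thr[node] = best_thr;
  int nl = add_node(t), nr = add_node(t);
  t.left[node] = nl;
  t.right[node] = nr;
  grow(t, nl, X, y, idx, lo, mid, depth + 1, max_depth, mtry, pool, feats, buf);
  grow(t, nr, X, y, idx, mid, hi, depth + 1, max_depth, mtry, pool, feats, buf);
}

int predict_one(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.var[node] >= 0)
    node = (X(row, t.var[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

}  // namespace

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(NumericMatrix X, IntegerVector y,
                             NumericMatrix Xtest,
                             int n_tree, int mtry, int max_depth) {
  const int n = X.nrow(), ntest = Xtest.nrow();
  std::vector<int> votes(ntest, 0);
  std::vector<int> idx(n);
  std::vector<int> pool(X.ncol()), feats;
  std::vector< std::pair<double, int> > buf;

  for (int b = 0; b < n_tree; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = (int) (unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
    }
    Tree t;
    add_node(t);
    grow(t, 0, X, y, idx, 0, n, 0, max_depth, mtry, pool, feats, buf);
    for (int i = 0; i < ntest; ++i) votes[i] += predict_one(t, Xtest, i);
  }

  IntegerVector out(ntest);
  for (int i = 0; i < ntest; ++i) out[i] = (2 * votes[i] > n_tree) ? 1 : 0;
  return out;
}
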