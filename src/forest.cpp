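// Random-forest classifier backend: gini CART trees grown on bootstrap
// resamples with sqrt(p) feature subsampling, class probabilities averaged
// over trees. Self-contained because the deployment image ships no tree
// learner; defaults mirror the common scikit-learn RandomForestClassifier
// settings (unbounded depth, min_samples_split = 2).

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feat, left, right;
  std::vector<double> thr, prob;
};

int grow(const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& samples, int lo, int hi, int depth, int mtry,
         int min_split, int max_depth, std::mt19937& rng, TreeBuf& T,
         std::vector<int>& featpool) {
  const int node = static_cast<int>(T.feat.size());
  T.feat.push_back(-1);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.thr.push_back(0.0);
  T.prob.push_back(0.0);

  const int n = hi - lo;
  int npos = 0;
  for (int i = lo; i < hi; ++i) npos += y[samples[i]];
  T.prob[node] = static_cast<double>(npos) / n;
  if (npos == 0 || npos == n || n < min_split || depth >= max_depth)
    return node;

  const int p = X.ncol();
  const double parent =
      static_cast<double>(n) *
      (1.0 - (static_cast<double>(npos) * npos +
              static_cast<double>(n - npos) * (n - npos)) /
                 (static_cast<double>(n) * n));

  double best = parent - 1e-12;  // require strictly positive gini decrease
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  for (int t = 0; t < mtry; ++t) {
    std::uniform_int_distribution<int> uni(t, p - 1);
    std::swap(featpool[t], featpool[uni(rng)]);
    const int f = featpool[t];
    for (int i = 0; i < n; ++i) {
      const int s = samples[lo + i];
      vals[i] = {X(s, f), y[s]};
    }
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int lpos = 0;
    for (int i = 1; i < n; ++i) {
      lpos += vals[i - 1].second;
      if (vals[i].first == vals[i - 1].first) continue;
      const int ln = i, rn = n - i, rpos = npos - lpos;
      const double gl =
          ln * (1.0 - (static_cast<double>(lpos) * lpos +
                       static_cast<double>(ln - lpos) * (ln - lpos)) /
                          (static_cast<double>(ln) * ln));
      const double gr =
          rn * (1.0 - (static_cast<double>(rpos) * rpos +
                       static_cast<double>(rn - rpos) * (rn - rpos)) /
                          (static_cast<double>(rn) * rn));
      if (gl + gr < best) {
        best = gl + gr;
        best_f = f;
        best_thr = 0.5 * (vals[i - 1].first + vals[i].first);
      }
    }
  }
  if (best_f < 0) return node;

  std::vector<int>::iterator first = samples.begin() + lo,
                             last = samples.begin() + hi;
  std::vector<int>::iterator mid = std::stable_partition(
      first, last,
      [&](int s) { return X(s, best_f) <= best_thr; });
  const int cut = static_cast<int>(mid - samples.begin());
  if (cut == lo || cut == hi) return node;  // numerically degenerate split

  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  T.left[node] = grow(X, y, samples, lo, cut, depth + 1, mtry, min_split,
                      max_depth, rng, T, featpool);
  T.right[node] = grow(X, y, samples, cut, hi, depth + 1, mtry, min_split,
                       max_depth, rng, T, featpool);
  return node;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_split, int max_depth, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  List trees(ntree);
  std::vector<int> featpool(p);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> samples(n);
    std::uniform_int_distribution<int> boot(0, n - 1);
    for (int i = 0; i < n; ++i) samples[i] = boot(rng);
    std::iota(featpool.begin(), featpool.end(), 0);
    TreeBuf T;
    grow(X, y, samples, 0, n, 0, mtry, min_split, max_depth, rng, T,
         featpool);
    trees[t] =
        List::create(_["feat"] = wrap(T.feat), _["thr"] = wrap(T.thr),
                     _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                     _["prob"] = wrap(T.prob));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += prob[node];
    }
  }
  return out / ntree;
}
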