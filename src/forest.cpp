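// Regression random forest with variance-reduction splits.
//
// Importance of a split is the decrease in variance IV = n*dp - n1*dc1 - n2*dc2
// with population variances, i.e. the parent sum of squared deviations minus
// the children's.  Trees are grown until every leaf is pure (or its rows are
// indistinguishable), a tree's per-feature importance is the sum of IV over
// the nodes splitting on that feature, and the forest importance is the mean
// over trees.  All randomness comes from one 64-bit stream seeded by the
// caller, so a (X, y, params, seed) tuple maps to one importance vector.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNode {
  int feature;     // 0-based split feature; -1 for a leaf
  double threshold;
  int n, n1, n2;
  double iv;
  int left, right; // 0-based node ids; -1 for a leaf
  double value;    // node mean of y
};

struct BestSplit {
  int feature = -1;
  double threshold = 0.0;
  double iv = -1.0;
  int n_left = 0;
};

class RNG {
  std::uint64_t s;
public:
  explicit RNG(std::uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  // splitmix64: small, fast, and stable across platforms
  std::uint64_t next() {
    std::uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (std::uint64_t)n); }
};

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const NumericVector& y, int mtry, RNG& rng)
      : X_(X), y_(y), p_(X.ncol()), mtry_(mtry), rng_(rng), perm_(p_) {
    for (int j = 0; j < p_; ++j) perm_[j] = j;
  }

  // samples: bootstrap row indices (0-based); modified in place by partitioning
  std::vector<TreeNode> build(std::vector<int>& samples,
                              std::vector<double>& tree_imp) {
    nodes_.clear();
    samples_ = &samples;
    grow(0, (int)samples.size(), tree_imp);
    return nodes_;
  }

private:
  const NumericMatrix& X_;
  const NumericVector& y_;
  int p_, mtry_;
  RNG& rng_;
  std::vector<int> perm_;
  std::vector<TreeNode> nodes_;
  std::vector<int>* samples_ = nullptr;
  std::vector<std::pair<double, double>> buf_; // (x, y) pairs of the node

  // best split for one feature over samples [start, end)
  void scan_feature(int f, int start, int end, double ss_parent, BestSplit& best) {
    const std::vector<int>& smp = *samples_;
    const double* xcol = &X_[0] + (std::size_t)f * X_.nrow();
    int m = end - start;
    buf_.resize(m);
    double sy = 0.0, syy = 0.0;
    double xmin = xcol[smp[start]], xmax = xmin;
    for (int i = 0; i < m; ++i) {
      double x = xcol[smp[start + i]];
      double v = y_[smp[start + i]];
      buf_[i] = {x, v};
      sy += v;
      syy += v * v;
      if (x < xmin) xmin = x;
      if (x > xmax) xmax = x;
    }
    if (xmin == xmax) return; // constant feature
    // only the x ordering matters: within ties the y order does not change
    // the prefix sums at any valid split boundary
    std::sort(buf_.begin(), buf_.end());
    double cy = 0.0, cyy = 0.0;
    for (int i = 1; i < m; ++i) {
      double v = buf_[i - 1].second;
      cy += v;
      cyy += v * v;
      double x_lo = buf_[i - 1].first, x_hi = buf_[i].first;
      if (x_lo == x_hi) continue;
      double n1 = (double)i, n2 = (double)(m - i);
      double ss1 = cyy - cy * cy / n1;
      double ss2 = (syy - cyy) - (sy - cy) * (sy - cy) / n2;
      double iv = ss_parent - ss1 - ss2;
      if (iv > best.iv) {
        double thr = (x_lo + x_hi) / 2.0;
        if (!(thr >= x_lo && thr < x_hi)) thr = x_lo; // adjacent doubles
        best.iv = iv;
        best.feature = f;
        best.threshold = thr;
        best.n_left = i;
      }
    }
  }

  int grow(int start, int end, std::vector<double>& tree_imp) {
    std::vector<int>& smp = *samples_;
    int m = end - start;
    double sy = 0.0;
    double ymin = y_[smp[start]], ymax = ymin;
    for (int i = start; i < end; ++i) {
      double v = y_[smp[i]];
      sy += v;
      if (v < ymin) ymin = v;
      if (v > ymax) ymax = v;
    }
    double mean = sy / m;

    int id = (int)nodes_.size();
    nodes_.push_back(TreeNode{-1, 0.0, m, 0, 0, 0.0, -1, -1, mean});
    if (m < 2 || ymin == ymax) return id; // pure leaf

    double ss_parent = 0.0;
    for (int i = start; i < end; ++i) {
      double d = y_[smp[i]] - mean;
      ss_parent += d * d;
    }

    // draw mtry candidate features without replacement; scan in ascending
    // index order so equal-IV ties resolve to the lowest feature index
    int k = std::min(mtry_, p_);
    for (int j = 0; j < k; ++j) std::swap(perm_[j], perm_[j + rng_.below(p_ - j)]);
    std::vector<int> cand(perm_.begin(), perm_.begin() + k);
    std::sort(cand.begin(), cand.end());

    BestSplit best;
    for (int f : cand) scan_feature(f, start, end, ss_parent, best);
    if (best.feature < 0) {
      // all sampled candidates constant: fall back to every feature so a leaf
      // stays impure only when its rows are indistinguishable
      for (int f = 0; f < p_; ++f) scan_feature(f, start, end, ss_parent, best);
      if (best.feature < 0) return id; // identical predictor rows
    }

    double iv = best.iv > 0.0 ? best.iv : 0.0; // clip float negatives
    tree_imp[best.feature] += iv;

    // partition in place, stably, by the chosen split
    std::stable_partition(smp.begin() + start, smp.begin() + end,
                          [&](int a) { return X_(a, best.feature) <= best.threshold; });
    int mid = start + best.n_left;

    nodes_[id].feature = best.feature;
    nodes_[id].threshold = best.threshold;
    nodes_[id].n1 = best.n_left;
    nodes_[id].n2 = m - best.n_left;
    nodes_[id].iv = iv;
    int left = grow(start, mid, tree_imp);
    int right = grow(mid, end, tree_imp);
    nodes_[id].left = left;
    nodes_[id].right = right;
    return id;
  }
};

List pack_tree(const std::vector<TreeNode>& nodes, const std::vector<int>& inbag) {
  int nn = (int)nodes.size();
  IntegerVector feature(nn), n(nn), n1(nn), n2(nn), left(nn), right(nn);
  NumericVector threshold(nn), iv(nn), value(nn);
  for (int i = 0; i < nn; ++i) {
    const TreeNode& nd = nodes[i];
    feature[i] = nd.feature >= 0 ? nd.feature + 1 : NA_INTEGER;
    threshold[i] = nd.feature >= 0 ? nd.threshold : NA_REAL;
    n[i] = nd.n;
    n1[i] = nd.n1;
    n2[i] = nd.n2;
    iv[i] = nd.iv;
    left[i] = nd.left >= 0 ? nd.left + 1 : NA_INTEGER;
    right[i] = nd.right >= 0 ? nd.right + 1 : NA_INTEGER;
    value[i] = nd.value;
  }
  IntegerVector ib(inbag.size());
  for (size_t i = 0; i < inbag.size(); ++i) ib[i] = inbag[i] + 1;
  return List::create(_["inbag"] = ib, _["feature"] = feature,
                      _["threshold"] = threshold, _["n"] = n, _["n1"] = n1,
                      _["n2"] = n2, _["iv"] = iv, _["left"] = left,
                      _["right"] = right, _["value"] = value);
}

} // namespace

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int bootstrap_size, bool bootstrap, double seed,
                    bool keep_forest) {
  int n = X.nrow(), p = X.ncol();
  RNG rng((std::uint64_t)seed);
  TreeBuilder builder(X, y, mtry, rng);

  std::vector<double> forest_imp(p, 0.0), tree_imp(p);
  List trees(keep_forest ? ntree : 0);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> samples;
    if (bootstrap) {
      samples.resize(bootstrap_size);
      for (int i = 0; i < bootstrap_size; ++i) samples[i] = rng.below(n);
    } else {
      samples.resize(n);
      for (int i = 0; i < n; ++i) samples[i] = i;
    }
    std::vector<int> inbag = samples;
    std::fill(tree_imp.begin(), tree_imp.end(), 0.0);
    std::vector<TreeNode> nodes = builder.build(samples, tree_imp);
    for (int j = 0; j < p; ++j) forest_imp[j] += tree_imp[j];
    if (keep_forest) trees[t] = pack_tree(nodes, inbag);
  }

  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = forest_imp[j] / ntree;
  return List::create(_["importance"] = imp,
                      _["trees"] = keep_forest ? (SEXP)trees : R_NilValue);
}
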