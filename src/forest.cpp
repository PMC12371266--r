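// Deterministic histogram-based random forest for binary classification.
//
// Features are pre-binned into at most `max_bins` quantile bins per feature,
// so split search at a node costs O(n_node * mtry + bins) instead of a sort.
// All randomness flows from one 64-bit seed through a splitmix64 generator;
// trees are grown sequentially, so results are reproducible across platforms.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n); n > 0
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double gini(double npos, double ntot) {
  if (ntot <= 0.0) return 0.0;
  const double p = npos / ntot;
  return 2.0 * p * (1.0 - p);
}

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> pred;      // leaf positive fraction

  int add_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct Task {
  int node, lo, hi, depth;
};

} // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix x, IntegerVector y, int num_trees, int mtry,
                  int min_node_size, int max_depth, int max_bins, double seed) {
  const int n = x.nrow(), p = x.ncol();
  if (n < 2) stop("need at least 2 samples");
  if (mtry < 1 || mtry > p) stop("mtry out of range");

  // --- per-feature quantile binning -------------------------------------
  std::vector<std::vector<double>> thresholds(p);
  std::vector<uint16_t> binned(static_cast<size_t>(n) * p);
  std::vector<double> col(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = x(i, j);
    std::vector<double> sorted(col);
    std::sort(sorted.begin(), sorted.end());
    std::vector<double> uniq(sorted);
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    std::vector<double> thr;
    if (static_cast<int>(uniq.size()) <= max_bins) {
      for (size_t k = 1; k < uniq.size(); ++k)
        thr.push_back(0.5 * (uniq[k - 1] + uniq[k]));
    } else {
      std::vector<double> qv;
      for (int b = 1; b < max_bins; ++b) {
        size_t idx = static_cast<size_t>(
            (static_cast<double>(b) * n) / max_bins);
        if (idx >= static_cast<size_t>(n)) idx = n - 1;
        qv.push_back(sorted[idx]);
      }
      qv.erase(std::unique(qv.begin(), qv.end()), qv.end());
      for (size_t k = 0; k < qv.size(); ++k) {
        // midpoint between the quantile value and its predecessor value
        double lo = qv[k];
        auto it = std::lower_bound(uniq.begin(), uniq.end(), qv[k]);
        if (it != uniq.begin()) lo = *(it - 1);
        double t = 0.5 * (lo + qv[k]);
        if (thr.empty() || t > thr.back()) thr.push_back(t);
      }
    }
    // bin(x) = number of thresholds < x; x <= thr[b]  <=>  bin(x) <= b
    for (int i = 0; i < n; ++i) {
      int b = static_cast<int>(
          std::lower_bound(thr.begin(), thr.end(), col[i]) - thr.begin());
      binned[static_cast<size_t>(j) * n + i] = static_cast<uint16_t>(b);
    }
    thresholds[j] = thr;
  }

  SplitMix64 rng(static_cast<uint64_t>(seed));
  std::vector<double> importance(p, 0.0);

  const int nbins = max_bins + 1;
  std::vector<int> cnt(nbins), pos(nbins);
  std::vector<int> idx(n), chosen(mtry);

  List trees(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    // bootstrap sample
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);

    TreeBuf tb;
    std::vector<Task> stack;
    stack.push_back({tb.add_node(), 0, n, 0});

    while (!stack.empty()) {
      Task tk = stack.back();
      stack.pop_back();
      const int lo = tk.lo, hi = tk.hi, m = hi - lo;
      int npos = 0;
      for (int i = lo; i < hi; ++i) npos += y[idx[i]];

      const bool stop_here = (m < 2 * min_node_size) || npos == 0 ||
                             npos == m ||
                             (max_depth > 0 && tk.depth >= max_depth);
      if (!stop_here) {
        const double imp_parent = gini(npos, m);
        double best_gain = 1e-12;
        int best_feat = -1, best_bin = -1;
        double best_nl = 0;

        // sample mtry distinct features (rejection; mtry << p)
        for (int k = 0; k < mtry; ++k) {
          int f;
          bool dup;
          do {
            f = rng.unif_int(p);
            dup = false;
            for (int q = 0; q < k; ++q)
              if (chosen[q] == f) { dup = true; break; }
          } while (dup);
          chosen[k] = f;
        }

        for (int k = 0; k < mtry; ++k) {
          const int f = chosen[k];
          const int nb = static_cast<int>(thresholds[f].size()) + 1;
          if (nb < 2) continue;
          std::fill(cnt.begin(), cnt.begin() + nb, 0);
          std::fill(pos.begin(), pos.begin() + nb, 0);
          const uint16_t *bcol = &binned[static_cast<size_t>(f) * n];
          for (int i = lo; i < hi; ++i) {
            const int b = bcol[idx[i]];
            ++cnt[b];
            pos[b] += y[idx[i]];
          }
          int cl = 0, pl = 0;
          for (int b = 0; b < nb - 1; ++b) {
            cl += cnt[b];
            pl += pos[b];
            if (cl == 0 || cl == m) continue;
            const int cr = m - cl, pr = npos - pl;
            const double gain = imp_parent -
                (cl * gini(pl, cl) + cr * gini(pr, cr)) / m;
            if (gain > best_gain) {
              best_gain = gain;
              best_feat = f;
              best_bin = b;
              best_nl = cl;
            }
          }
        }

        if (best_feat >= 0) {
          importance[best_feat] += (static_cast<double>(m) / n) * best_gain;
          const uint16_t *bcol = &binned[static_cast<size_t>(best_feat) * n];
          const int bsplit = best_bin;
          std::stable_partition(idx.begin() + lo, idx.begin() + hi,
                                [&](int i) { return bcol[i] <= bsplit; });
          const int mid = lo + static_cast<int>(best_nl);
          tb.feature[tk.node] = best_feat;
          tb.threshold[tk.node] = thresholds[best_feat][best_bin];
          const int lnode = tb.add_node();
          const int rnode = tb.add_node();
          tb.left[tk.node] = lnode;
          tb.right[tk.node] = rnode;
          // push right first so left is processed first (cosmetic determinism)
          stack.push_back({rnode, mid, hi, tk.depth + 1});
          stack.push_back({lnode, lo, mid, tk.depth + 1});
          continue;
        }
      }
      tb.pred[tk.node] = static_cast<double>(npos) / m;
    }

    trees[t] = List::create(
        _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
        _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
        _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
        _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
        _["pred"] = NumericVector(tb.pred.begin(), tb.pred.end()));
  }

  NumericVector imp(importance.begin(), importance.end());
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["num_trees"] = num_trees);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix x) {
  List trees = forest["trees"];
  const int n = x.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (x(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += pred[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
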