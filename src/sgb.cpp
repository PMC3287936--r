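// Stochastic gradient boosting core for a binary outcome: binomial-deviance
// loss, least-squares regression trees grown best-first on histogram-binned
// features, one-step Newton leaf values, row subsampling without
// replacement via the R RNG (so set.seed() in R fixes the whole fit).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int MAX_BINS = 64;
const double EPS_GAIN = 1e-12;
const double EPS_HESS = 1e-6;

struct FeatureBins {
  std::vector<double> cuts;  // split thresholds; bin b <=> value <= cuts[b]
  int nbins;
};

// Quantile-style binning; exact for features with <= MAX_BINS distinct values
// (covers 0/1/2 dosages), midpoint thresholds between adjacent bin edges.
FeatureBins make_bins(const NumericVector& col) {
  std::vector<double> v(col.begin(), col.end());
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  FeatureBins fb;
  if ((int)v.size() <= MAX_BINS) {
    for (size_t i = 0; i + 1 < v.size(); ++i)
      fb.cuts.push_back(0.5 * (v[i] + v[i + 1]));
  } else {
    for (int b = 1; b < MAX_BINS; ++b) {
      size_t idx = (size_t)((double)b * v.size() / MAX_BINS);
      if (idx >= v.size() - 1) idx = v.size() - 2;
      double cut = 0.5 * (v[idx] + v[idx + 1]);
      if (fb.cuts.empty() || cut > fb.cuts.back()) fb.cuts.push_back(cut);
    }
  }
  fb.nbins = (int)fb.cuts.size() + 1;
  return fb;
}

struct Node {
  std::vector<int> rows;     // sampled row indices in this node
  double sum_r = 0, sum_h = 0;
  int tree_idx = -1;         // index in the flat tree arrays
  int best_feat = -1, best_bin = -1;
  double best_gain = 0;
};

struct Split { int feat; int bin; double gain; };

// Best squared-error-reduction split of a node over all features/bins.
void find_best(Node& nd, const IntegerMatrix& binidx, const NumericVector& r,
               const std::vector<FeatureBins>& bins, int min_node,
               std::vector<double>& cnt, std::vector<double>& sum) {
  int p = binidx.ncol();
  nd.best_feat = -1; nd.best_bin = -1; nd.best_gain = 0;
  double n_tot = (double)nd.rows.size();
  if (n_tot < 2 * min_node) return;
  double parent = nd.sum_r * nd.sum_r / n_tot;
  for (int f = 0; f < p; ++f) {
    int nb = bins[f].nbins;
    if (nb < 2) continue;
    std::fill(cnt.begin(), cnt.begin() + nb, 0.0);
    std::fill(sum.begin(), sum.begin() + nb, 0.0);
    for (int i : nd.rows) {
      int b = binidx(i, f);
      cnt[b] += 1.0;
      sum[b] += r[i];
    }
    double cl = 0, sl = 0;
    for (int b = 0; b + 1 < nb; ++b) {
      cl += cnt[b]; sl += sum[b];
      double cr = n_tot - cl, sr = nd.sum_r - sl;
      if (cl < min_node || cr < min_node) continue;
      double gain = sl * sl / cl + sr * sr / cr - parent;
      if (gain > nd.best_gain + EPS_GAIN) {
        nd.best_gain = gain;
        nd.best_feat = f;
        nd.best_bin = b;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List sgb_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int max_leaves,
                 double shrinkage, double subsample, int min_node) {
  int n = X.nrow(), p = X.ncol();

  std::vector<FeatureBins> bins(p);
  IntegerMatrix binidx(n, p);
  for (int f = 0; f < p; ++f) {
    bins[f] = make_bins(X(_, f));
    const std::vector<double>& cuts = bins[f].cuts;
    for (int i = 0; i < n; ++i) {
      binidx(i, f) = (int)(std::lower_bound(cuts.begin(), cuts.end(), X(i, f)) -
                           cuts.begin());
    }
  }

  double ybar = mean(y);
  double base = std::log(ybar / (1.0 - ybar));
  NumericVector F(n, base);
  NumericVector importance(p);
  List trees(n_trees);

  int m = std::max(1, (int)std::floor(subsample * n));
  std::vector<double> cnt(MAX_BINS), sum(MAX_BINS);
  NumericVector r(n), h(n);

  for (int t = 0; t < n_trees; ++t) {
    IntegerVector samp = Rcpp::sample(n, m, false);  // 1-based, uses R RNG

    for (int i = 0; i < n; ++i) {
      double prob = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - prob;
      h[i] = prob * (1.0 - prob);
    }

    // flat tree arrays
    std::vector<int> t_feat, t_left, t_right;
    std::vector<double> t_thr, t_val;
    std::vector<Node> nodes(1);
    nodes[0].rows.reserve(m);
    for (int k = 0; k < m; ++k) {
      int i = samp[k] - 1;
      nodes[0].rows.push_back(i);
      nodes[0].sum_r += r[i];
      nodes[0].sum_h += h[i];
    }
    nodes[0].tree_idx = 0;
    t_feat.push_back(-1); t_thr.push_back(0);
    t_left.push_back(-1); t_right.push_back(-1); t_val.push_back(0);
    find_best(nodes[0], binidx, r, bins, min_node, cnt, sum);

    std::vector<int> open = {0};  // splittable leaves (indices into nodes)
    int n_leaves = 1;
    while (n_leaves < max_leaves) {
      int pick = -1;
      double best = EPS_GAIN;
      for (int idx : open) {
        if (nodes[idx].best_feat >= 0 && nodes[idx].best_gain > best) {
          best = nodes[idx].best_gain;
          pick = idx;
        }
      }
      if (pick < 0) break;

      Node& nd = nodes[pick];
      int f = nd.best_feat, b = nd.best_bin;
      importance[f] += nd.best_gain;

      Node lhs, rhs;
      for (int i : nd.rows) {
        if (binidx(i, f) <= b) {
          lhs.rows.push_back(i); lhs.sum_r += r[i]; lhs.sum_h += h[i];
        } else {
          rhs.rows.push_back(i); rhs.sum_r += r[i]; rhs.sum_h += h[i];
        }
      }
      int ti = nd.tree_idx;
      t_feat[ti] = f;
      t_thr[ti] = bins[f].cuts[b];
      lhs.tree_idx = (int)t_feat.size();
      t_feat.push_back(-1); t_thr.push_back(0);
      t_left.push_back(-1); t_right.push_back(-1); t_val.push_back(0);
      rhs.tree_idx = (int)t_feat.size();
      t_feat.push_back(-1); t_thr.push_back(0);
      t_left.push_back(-1); t_right.push_back(-1); t_val.push_back(0);
      t_left[ti] = lhs.tree_idx;
      t_right[ti] = rhs.tree_idx;

      find_best(lhs, binidx, r, bins, min_node, cnt, sum);
      find_best(rhs, binidx, r, bins, min_node, cnt, sum);
      int pick_pos = -1;
      for (size_t q = 0; q < open.size(); ++q)
        if (open[q] == pick) { pick_pos = (int)q; break; }
      nodes.push_back(lhs);
      int lhs_idx = (int)nodes.size() - 1;
      nodes.push_back(rhs);
      int rhs_idx = (int)nodes.size() - 1;
      open[pick_pos] = lhs_idx;
      open.push_back(rhs_idx);
      ++n_leaves;
    }

    // one-step Newton leaf values
    for (Node& nd : nodes) {
      int ti = nd.tree_idx;
      if (t_feat[ti] != -1) continue;  // internal node
      t_val[ti] = nd.sum_r / std::max(nd.sum_h, EPS_HESS);
    }

    // route every row (not just the subsample) through the tree
    int n_nodes = (int)t_feat.size();
    NumericMatrix tree(n_nodes, 5);
    for (int k = 0; k < n_nodes; ++k) {
      tree(k, 0) = t_feat[k];
      tree(k, 1) = t_thr[k];
      tree(k, 2) = t_left[k];
      tree(k, 3) = t_right[k];
      tree(k, 4) = t_val[k];
    }
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (t_feat[k] >= 0)
        k = X(i, t_feat[k]) <= t_thr[k] ? t_left[k] : t_right[k];
      F[i] += shrinkage * t_val[k];
    }
    trees[t] = tree;
  }

  return List::create(_["base_score"] = base, _["trees"] = trees,
                      _["importance"] = importance, _["train_score"] = F);
}

// [[Rcpp::export]]
NumericVector sgb_predict_cpp(List trees, NumericMatrix X, double base_score,
                              double shrinkage) {
  int n = X.nrow();
  NumericVector F(n, base_score);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (tree(k, 0) >= 0)
        k = X(i, (int)tree(k, 0)) <= tree(k, 1) ? (int)tree(k, 2)
                                                : (int)tree(k, 3);
      F[i] += shrinkage * tree(k, 4);
    }
  }
  return F;
}
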