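// Extremely randomized trees (ExtraTrees) regression.
//
// Each tree is grown on the full sample (no bootstrap). At every node a
// random subset of mtry features is drawn; for each candidate feature a
// single uniform random cut point between the node's min and max is drawn,
// and the candidate with the largest variance reduction is kept. Trees are
// grown until nodes are pure or smaller than min_split, so an unconstrained
// forest interpolates its training data. Impurity-decrease feature
// importances are accumulated per split.

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1: leaf
  double split = 0.0;
  int left = -1, right = -1;
  double value = 0.0;     // leaf mean
};

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_split;
  std::mt19937_64& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;
  std::vector<int> feat_buf;

  TreeBuilder(const NumericMatrix& X, const NumericVector& y, int mtry,
              int min_split, std::mt19937_64& rng,
              std::vector<double>& importance)
      : X(X), y(y), mtry(mtry), min_split(min_split), rng(rng),
        importance(importance) {
    feat_buf.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_buf[j] = j;
  }

  int build(std::vector<int>& idx, int lo, int hi) {
    const int n = hi - lo;
    double sum = 0.0, sumsq = 0.0;
    for (int t = lo; t < hi; ++t) {
      sum += y[idx[t]];
      sumsq += y[idx[t]] * y[idx[t]];
    }
    const double mean = sum / n;
    const double sse = sumsq - sum * sum / n;

    int id = (int)nodes.size();
    nodes.emplace_back();
    nodes[id].value = mean;
    if (n < min_split || sse <= 1e-12 * (std::abs(sumsq) + 1.0)) return id;

    // draw mtry distinct candidate features (partial Fisher-Yates)
    const int p = X.ncol();
    for (int t = 0; t < mtry; ++t) {
      std::uniform_int_distribution<int> d(t, p - 1);
      std::swap(feat_buf[t], feat_buf[d(rng)]);
    }

    int best_feat = -1;
    double best_split = 0.0, best_score = -1.0;
    for (int t = 0; t < mtry; ++t) {
      const int j = feat_buf[t];
      double mn = R_PosInf, mx = R_NegInf;
      for (int q = lo; q < hi; ++q) {
        const double v = X(idx[q], j);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (!(mx > mn)) continue;
      std::uniform_real_distribution<double> d(mn, mx);
      double cut = d(rng);
      if (!(cut > mn)) cut = std::nextafter(mn, mx);  // keep both sides non-empty
      double lsum = 0.0, lsq = 0.0;
      int ln = 0;
      for (int q = lo; q < hi; ++q) {
        const double yi = y[idx[q]];
        if (X(idx[q], j) <= cut) {
          lsum += yi;
          lsq += yi * yi;
          ++ln;
        }
      }
      const int rn = n - ln;
      if (ln == 0 || rn == 0) continue;
      const double rsum = sum - lsum, rsq = sumsq - lsq;
      const double child_sse =
          (lsq - lsum * lsum / ln) + (rsq - rsum * rsum / rn);
      const double score = sse - child_sse;
      if (score > best_score) {
        best_score = score;
        best_feat = j;
        best_split = cut;
      }
    }
    if (best_feat < 0) return id;

    // partition idx[lo:hi) in place
    int mid = lo;
    for (int q = lo; q < hi; ++q) {
      if (X(idx[q], best_feat) <= best_split) std::swap(idx[q], idx[mid++]);
    }
    importance[best_feat] += best_score;
    nodes[id].feature = best_feat;
    nodes[id].split = best_split;
    const int l = build(idx, lo, mid);
    const int r = build(idx, mid, hi);
    nodes[id].feature = best_feat;  // nodes may have been reallocated
    nodes[id].split = best_split;
    nodes[id].left = l;
    nodes[id].right = r;
    nodes[id].value = mean;
    return id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".et_fit")]]
List et_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
            int min_split, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(x)");
  if (n < 1) stop("need at least one training row");
  if (mtry < 1 || mtry > p) stop("mtry must be in 1..ncol(x)");
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  std::vector<int> idx(n);
  for (int b = 0; b < n_trees; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    TreeBuilder tb(X, y, mtry, min_split, rng, importance);
    tb.nodes.reserve(2 * n);
    tb.build(idx, 0, n);
    const int m = (int)tb.nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector split(m), value(m);
    for (int k = 0; k < m; ++k) {
      feature[k] = tb.nodes[k].feature;
      split[k] = tb.nodes[k].split;
      left[k] = tb.nodes[k].left;
      right[k] = tb.nodes[k].right;
      value[k] = tb.nodes[k].value;
    }
    trees[b] = List::create(_["feature"] = feature, _["split"] = split,
                            _["left"] = left, _["right"] = right,
                            _["value"] = value);
  }
  double tot = 0.0;
  for (double v : importance) tot += v;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["n_features"] = p);
}

// [[Rcpp::export(name = ".et_predict")]]
NumericVector et_predict(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int p = as<int>(forest["n_features"]);
  if (X.ncol() != p) stop("feature count mismatch");
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector split = tr["split"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (feature[k] >= 0) {
        k = X(i, feature[k]) <= split[k] ? left[k] : right[k];
      }
      out[i] += value[k];
    }
  }
  return out / (double)B;
}
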