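// Random forest for binary (0/1) feature matrices.
//
// CART-style trees with Gini splits on x[j] == 0 vs x[j] == 1, bootstrap
// resampling per tree and a random feature subset (mtry) per node.  The
// forest's probability score is the mean of the per-tree leaf class-1
// proportions, matching the usual predict_proba convention of bagged
// tree ensembles.  No installed R package provides a random forest in
// this environment, hence this implementation.

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;   // -1 for leaf
  int left, right;
  double value;  // leaf class-1 proportion
};

struct TreeBuilder {
  const IntegerMatrix &X;  // n x p
  const IntegerVector &y;
  int mtry;
  std::mt19937_64 &rng;
  std::vector<Node> nodes;
  std::vector<int> featBuf;

  TreeBuilder(const IntegerMatrix &X_, const IntegerVector &y_, int mtry_,
              std::mt19937_64 &rng_)
      : X(X_), y(y_), mtry(mtry_), rng(rng_) {
    featBuf.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) featBuf[j] = j;
  }

  int build(std::vector<int> &idx) {
    int n = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    double p1 = (double)pos / n;
    Node node{-1, -1, -1, p1};
    if (pos == 0 || pos == n || n < 2) {
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    // sample mtry candidate features (partial Fisher-Yates)
    int p = X.ncol();
    int m = std::min(mtry, p);
    for (int k = 0; k < m; ++k) {
      std::uniform_int_distribution<int> d(k, p - 1);
      std::swap(featBuf[k], featBuf[d(rng)]);
    }
    double parentGini = 2.0 * p1 * (1.0 - p1);
    double bestGain = 1e-12;
    int bestFeat = -1;
    for (int k = 0; k < m; ++k) {
      int j = featBuf[k];
      int n1 = 0, pos1 = 0;
      for (int i : idx) {
        if (X(i, j) == 1) {
          ++n1;
          pos1 += y[i];
        }
      }
      int n0 = n - n1, pos0 = pos - pos1;
      if (n0 == 0 || n1 == 0) continue;
      double q0 = (double)pos0 / n0, q1 = (double)pos1 / n1;
      double childGini = (n0 * 2.0 * q0 * (1.0 - q0) +
                          n1 * 2.0 * q1 * (1.0 - q1)) / n;
      double gain = parentGini - childGini;
      if (gain > bestGain) {
        bestGain = gain;
        bestFeat = j;
      }
    }
    if (bestFeat < 0) {
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, bestFeat) == 1) ri.push_back(i); else li.push_back(i);
    }
    int self = (int)nodes.size();
    node.feature = bestFeat;
    nodes.push_back(node);
    int l = build(li);
    int r = build(ri);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

}  // namespace

// [[Rcpp::export(name = ".forestFit")]]
List forestFit(IntegerMatrix X, IntegerVector y, int ntree, int mtry,
               int seed) {
  int n = X.nrow();
  if (n != y.size()) stop("X/y size mismatch");
  std::mt19937_64 rng((uint64_t)seed);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::uniform_int_distribution<int> d(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = d(rng);
    TreeBuilder tb(X, y, mtry, rng);
    tb.build(idx);
    int nn = (int)tb.nodes.size();
    IntegerVector feat(nn), left(nn), right(nn);
    NumericVector val(nn);
    for (int i = 0; i < nn; ++i) {
      feat[i] = tb.nodes[i].feature;
      left[i] = tb.nodes[i].left;
      right[i] = tb.nodes[i].right;
      val[i] = tb.nodes[i].value;
    }
    trees[t] = List::create(_["feature"] = feat, _["left"] = left,
                            _["right"] = right, _["value"] = val);
  }
  return trees;
}

// [[Rcpp::export(name = ".forestPredict")]]
NumericVector forestPredict(List trees, IntegerMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector val = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = X(i, feat[node]) == 1 ? right[node] : left[node];
      out[i] += val[node];
    }
  }
  return out / (double)ntree;
}
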