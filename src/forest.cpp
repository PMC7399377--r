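// Breiman-style random forest for binary classification, written for the
// per-dyad speaker models: bagged CART trees with Gini splits and random
// feature subsetting, plus out-of-bag vote bookkeeping. Single-threaded
// and fully deterministic given the seed.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct FlatTree {
  std::vector<int> feat;     // -1 for leaf
  std::vector<double> thr;   // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<int> pred;     // leaf class (0/1), -1 for internal
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int p;
  int mtry;
  int minNode;
  std::mt19937& rng;
  FlatTree& tree;
  std::vector<int> featPool;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         int minNode_, std::mt19937& rng_, FlatTree& tree_)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), minNode(minNode_),
        rng(rng_), tree(tree_), featPool(p) {
    for (int j = 0; j < p; ++j) featPool[j] = j;
  }

  int newNode() {
    tree.feat.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(-1);
    return (int)tree.feat.size() - 1;
  }

  // grow on idx[lo, hi); returns node id
  int grow(std::vector<int>& idx, int lo, int hi) {
    int node = newNode();
    int n = hi - lo;
    int n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
    int n0 = n - n1;

    if (n0 == 0 || n1 == 0 || n < 2 * minNode) {
      tree.pred[node] = (n1 > n0) ? 1 : 0; // tie -> class 0 (P1)
      return node;
    }

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(featPool[j], featPool[d(rng)]);
    }

    int bestFeat = -1;
    double bestThr = 0.0, bestScore = -1.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < mtry; ++j) {
      int f = featPool[j];
      for (int i = 0; i < n; ++i) {
        vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
      }
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      int l1 = 0;
      for (int i = 1; i < n; ++i) {
        l1 += vals[i - 1].second;
        if (vals[i].first <= vals[i - 1].first) continue;
        int nl = i, nr = n - i;
        int r1 = n1 - l1;
        // decrease in Gini impurity ~ maximize sum of per-side purity
        double score = (double)(nl - 2.0 * l1 * (nl - l1) / (double)nl) +
                       (double)(nr - 2.0 * r1 * (nr - r1) / (double)nr);
        if (score > bestScore + 1e-12) {
          bestScore = score;
          bestFeat = f;
          bestThr = 0.5 * (vals[i].first + vals[i - 1].first);
        }
      }
    }

    if (bestFeat < 0) { // all sampled features constant on this node
      tree.pred[node] = (n1 > n0) ? 1 : 0;
      return node;
    }

    // partition idx[lo, hi) by the split, preserving order
    std::vector<int> leftIdx, rightIdx;
    leftIdx.reserve(n);
    rightIdx.reserve(n);
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], bestFeat) <= bestThr) leftIdx.push_back(idx[i]);
      else rightIdx.push_back(idx[i]);
    }
    std::copy(leftIdx.begin(), leftIdx.end(), idx.begin() + lo);
    std::copy(rightIdx.begin(), rightIdx.end(),
              idx.begin() + lo + (int)leftIdx.size());

    int mid = lo + (int)leftIdx.size();
    tree.feat[node] = bestFeat;
    tree.thr[node] = bestThr;
    tree.left[node] = grow(idx, lo, mid);
    tree.right[node] = grow(idx, mid, hi);
    return node;
  }
};

int treePredict(const FlatTree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feat[node] >= 0) {
    node = (X(row, t.feat[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

} // namespace

// [[Rcpp::export(name = ".rfTrain")]]
List rfTrain(NumericMatrix X, IntegerVector y, int nTrees, int mtry,
             int minNode, bool replace, double sampleFrac, int seed) {
  int n = X.nrow();
  std::mt19937 rng((uint32_t)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  List trees(nTrees);
  IntegerMatrix oobVotes(n, 2);
  std::vector<int> inBag(n);
  std::vector<int> idx;
  idx.reserve(n);

  int bagSize = replace ? n : std::max(1, (int)std::floor(sampleFrac * n));

  for (int t = 0; t < nTrees; ++t) {
    std::fill(inBag.begin(), inBag.end(), 0);
    idx.clear();
    if (replace) {
      for (int i = 0; i < n; ++i) {
        int k = pick(rng);
        idx.push_back(k);
        inBag[k] = 1;
      }
    } else {
      std::vector<int> perm(n);
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = 0; i < bagSize; ++i) {
        std::uniform_int_distribution<int> d(i, n - 1);
        std::swap(perm[i], perm[d(rng)]);
        idx.push_back(perm[i]);
        inBag[perm[i]] = 1;
      }
    }

    FlatTree tree;
    Grower g(X, y, mtry, minNode, rng, tree);
    g.grow(idx, 0, (int)idx.size());

    for (int i = 0; i < n; ++i) {
      if (!inBag[i]) oobVotes(i, treePredict(tree, X, i))++;
    }

    trees[t] = List::create(
        _["feat"] = IntegerVector(tree.feat.begin(), tree.feat.end()),
        _["thr"] = NumericVector(tree.thr.begin(), tree.thr.end()),
        _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
        _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
        _["pred"] = IntegerVector(tree.pred.begin(), tree.pred.end()));
  }

  return List::create(_["trees"] = trees, _["oobVotes"] = oobVotes);
}

// [[Rcpp::export(name = ".rfPredict")]]
IntegerMatrix rfPredict(List trees, NumericMatrix X) {
  int n = X.nrow();
  int nTrees = trees.size();
  IntegerMatrix votes(n, 2);
  for (int t = 0; t < nTrees; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      }
      votes(i, pred[node])++;
    }
  }
  return votes;
}
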