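// Small deterministic gradient-boosted decision trees for binary
// classification (logistic loss), leaf-wise growth with a leaf budget,
// exact greedy splits on presorted features. Matches the fixed
// hyperparameter regime used throughout the package (500 rounds, max 6
// leaves, learning rate 0.05) without an external boosting dependency.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0; // go left if x <= threshold
  int left = -1, right = -1;
  double value = 0.0;     // leaf output (already shrunk)
};

struct SplitInfo {
  double gain = 0.0;      // best split gain (<= 0: no usable split)
  int feature = -1;
  double threshold = 0.0;
};

struct LeafStat {
  int node = -1;          // index into the node vector
  double G = 0.0, H = 0.0;
  int count = 0;
  SplitInfo best;
};

// best split of one leaf, scanning presorted feature orders and skipping
// rows not in the leaf
SplitInfo best_split(const NumericMatrix& X,
                     const std::vector<std::vector<int>>& order,
                     const std::vector<int>& leaf_of, int leaf_id,
                     const std::vector<double>& g,
                     const std::vector<double>& h,
                     double G, double H, int count,
                     int min_data, double min_hess, double lambda) {
  SplitInfo best;
  const int p = X.ncol();
  const double parent = G * G / (H + lambda);
  for (int j = 0; j < p; ++j) {
    double GL = 0.0, HL = 0.0;
    int nL = 0;
    double prev_x = 0.0;
    bool have_prev = false;
    const std::vector<int>& ord = order[j];
    for (size_t k = 0; k < ord.size(); ++k) {
      int i = ord[k];
      if (leaf_of[i] != leaf_id) continue;
      double x = X(i, j);
      if (have_prev && x > prev_x) {
        int nR = count - nL;
        double GR = G - GL, HR = H - HL;
        if (nL >= min_data && nR >= min_data && HL >= min_hess &&
            HR >= min_hess) {
          double gain =
              0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                     parent);
          if (gain > best.gain) {
            best.gain = gain;
            best.feature = j;
            best.threshold = 0.5 * (prev_x + x);
          }
        }
      }
      GL += g[i];
      HL += h[i];
      ++nL;
      prev_x = x;
      have_prev = true;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".gbdt_fit_cpp")]]
List gbdt_fit_cpp(NumericMatrix X, NumericVector y, int nrounds,
                  int num_leaves, double learning_rate, int min_data_in_leaf,
                  double lambda, double min_hessian) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 rows");

  // presort feature columns once (stable: deterministic under ties)
  std::vector<std::vector<int>> order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const double* col = &X(0, j);
    std::stable_sort(order[j].begin(), order[j].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  double ybar = std::min(std::max(static_cast<double>(mean(y)), 1e-15),
                         1.0 - 1e-15);
  const double init = std::log(ybar / (1.0 - ybar));
  std::vector<double> score(n, init), g(n), h(n);
  std::vector<double> feat_gain(p, 0.0);
  List trees(nrounds);

  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-score[i]));
      g[i] = pr - y[i];
      h[i] = pr * (1.0 - pr);
    }

    std::vector<Node> nodes(1);
    std::vector<int> leaf_of(n, 0);
    std::vector<LeafStat> leaves(1);
    leaves[0].node = 0;
    for (int i = 0; i < n; ++i) {
      leaves[0].G += g[i];
      leaves[0].H += h[i];
    }
    leaves[0].count = n;
    leaves[0].best = best_split(X, order, leaf_of, 0, g, h, leaves[0].G,
                                leaves[0].H, n, min_data_in_leaf, min_hessian,
                                lambda);

    int n_leaves = 1;
    while (n_leaves < num_leaves) {
      // split the leaf with the largest positive gain (ties: lowest index)
      int pick = -1;
      double best_gain = 0.0;
      for (size_t l = 0; l < leaves.size(); ++l) {
        if (leaves[l].node >= 0 && leaves[l].best.feature >= 0 &&
            leaves[l].best.gain > best_gain) {
          best_gain = leaves[l].best.gain;
          pick = static_cast<int>(l);
        }
      }
      if (pick < 0) break;

      LeafStat& L = leaves[pick];
      int node_id = L.node;
      int fj = L.best.feature;
      double thr = L.best.threshold;
      feat_gain[fj] += L.best.gain;

      int left_id = static_cast<int>(nodes.size());
      nodes.emplace_back();
      nodes.emplace_back();
      nodes[node_id].feature = fj;
      nodes[node_id].threshold = thr;
      nodes[node_id].left = left_id;
      nodes[node_id].right = left_id + 1;

      LeafStat left, right;
      left.node = left_id;
      right.node = left_id + 1;
      // move membership: left keeps id `pick`, right gets a fresh id
      int right_leaf = static_cast<int>(leaves.size());
      for (int i = 0; i < n; ++i) {
        if (leaf_of[i] != pick) continue;
        if (X(i, fj) <= thr) {
          left.G += g[i];
          left.H += h[i];
          ++left.count;
        } else {
          leaf_of[i] = right_leaf;
          right.G += g[i];
          right.H += h[i];
          ++right.count;
        }
      }
      left.best = best_split(X, order, leaf_of, pick, g, h, left.G, left.H,
                             left.count, min_data_in_leaf, min_hessian,
                             lambda);
      right.best = best_split(X, order, leaf_of, right_leaf, g, h, right.G,
                              right.H, right.count, min_data_in_leaf,
                              min_hessian, lambda);
      leaves[pick] = left;
      leaves.push_back(right);
      ++n_leaves;
    }

    // leaf values + score update via membership
    std::vector<double> leaf_value(leaves.size(), 0.0);
    for (size_t l = 0; l < leaves.size(); ++l) {
      double v = -learning_rate * leaves[l].G / (leaves[l].H + lambda);
      nodes[leaves[l].node].value = v;
      leaf_value[l] = v;
    }
    for (int i = 0; i < n; ++i) score[i] += leaf_value[leaf_of[i]];

    NumericMatrix tm(static_cast<int>(nodes.size()), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature;
      tm(k, 1) = nodes[k].threshold;
      tm(k, 2) = nodes[k].left;
      tm(k, 3) = nodes[k].right;
      tm(k, 4) = nodes[k].value;
    }
    trees[round] = tm;
  }

  return List::create(_["init"] = init, _["trees"] = trees,
                      _["feature_gain"] = NumericVector(feat_gain.begin(),
                                                        feat_gain.end()));
}

// [[Rcpp::export(name = ".gbdt_predict_cpp")]]
NumericVector gbdt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  double init = as<double>(model["init"]);
  List trees = model["trees"];
  std::vector<double> score(n, init);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) >= 0) {
        int j = static_cast<int>(tm(node, 0));
        node = (X(i, j) <= tm(node, 1)) ? static_cast<int>(tm(node, 2))
                                        : static_cast<int>(tm(node, 3));
      }
      score[i] += tm(node, 4);
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-score[i]));
  return out;
}
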