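// Gradient-boosted decision trees with logistic loss: second-order boosting,
// exact greedy split search, depth-limited trees, L2 leaf regularisation.
// Deterministic: no subsampling, ties resolved to the lowest feature index
// and lowest threshold.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left when x < threshold
  int left, right;
  double value;     // leaf weight
};

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& grad;
  const std::vector<double>& hess;
  double lambda, gamma, min_child_weight;
  int max_depth;
  const std::vector<int>& features;   // columns this tree may split on
  std::vector<Node> nodes;
  std::vector<double>& importance;

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& g,
              const std::vector<double>& h, double lambda_, double gamma_,
              double mcw, int depth, const std::vector<int>& feats,
              std::vector<double>& imp)
      : X(X_), grad(g), hess(h), lambda(lambda_), gamma(gamma_),
        min_child_weight(mcw), max_depth(depth), features(feats),
        importance(imp) {}

  int build(std::vector<int>& idx, int depth) {
    double G = 0.0, H = 0.0;
    for (int i : idx) { G += grad[i]; H += hess[i]; }
    double leaf_val = -G / (H + lambda);

    int best_f = -1;
    double best_gain = 0.0, best_thr = 0.0;
    if (depth < max_depth && idx.size() >= 2) {
      const double parent_score = G * G / (H + lambda);
      std::vector<std::pair<double, int>> vals(idx.size());
      for (int f : features) {
        for (size_t k = 0; k < idx.size(); ++k)
          vals[k] = {X(idx[k], f), idx[k]};
        std::sort(vals.begin(), vals.end());
        double GL = 0.0, HL = 0.0;
        for (size_t k = 0; k + 1 < vals.size(); ++k) {
          GL += grad[vals[k].second];
          HL += hess[vals[k].second];
          if (vals[k + 1].first <= vals[k].first) continue; // tied values
          double HR = H - HL;
          if (HL < min_child_weight || HR < min_child_weight) continue;
          double GR = G - GL;
          double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                               - parent_score) - gamma;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
          }
        }
      }
    }

    int me = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, leaf_val});
    if (best_f < 0) return me;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) < best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return me;
    importance[best_f] += best_gain;
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

static double tree_predict(const NumericMatrix& tree, const NumericMatrix& X,
                           int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) < tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

// xorshift32: deterministic column subsampling independent of R's RNG
static inline uint32_t xs32(uint32_t& s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, int nrounds, double eta,
                   int max_depth, double lambda, double gamma,
                   double min_child_weight, double base_score,
                   double colsample_bytree, int sample_seed) {
  const int n = X.nrow(), p = X.ncol();
  double base_margin = std::log(base_score / (1.0 - base_score));
  std::vector<double> margin(n, base_margin), grad(n), hess(n);
  std::vector<double> importance(p, 0.0);
  List trees(nrounds);
  uint32_t rng = (uint32_t)sample_seed * 2654435761u + 88172645u;
  int n_cols = std::max(1, (int)std::ceil(colsample_bytree * p));

  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double prob = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = prob - y[i];
      hess[i] = std::max(prob * (1.0 - prob), 1e-16);
    }
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    if (n_cols < p) {                       // partial Fisher-Yates
      for (int k = 0; k < n_cols; ++k) {
        int j = k + (int)(xs32(rng) % (uint32_t)(p - k));
        std::swap(feats[k], feats[j]);
      }
      feats.resize(n_cols);
      std::sort(feats.begin(), feats.end());
    }
    TreeBuilder tb(X, grad, hess, lambda, gamma, min_child_weight, max_depth,
                   feats, importance);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    tb.build(idx, 0);

    NumericMatrix tm(tb.nodes.size(), 5);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      tm(k, 0) = tb.nodes[k].feature;
      tm(k, 1) = tb.nodes[k].threshold;
      tm(k, 2) = tb.nodes[k].left;
      tm(k, 3) = tb.nodes[k].right;
      tm(k, 4) = tb.nodes[k].value;
    }
    trees[round] = tm;
    for (int i = 0; i < n; ++i) margin[i] += eta * tree_predict(tm, X, i);
  }

  return List::create(_["trees"] = trees,
                      _["base_margin"] = base_margin,
                      _["eta"] = eta,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".gbt_margin_cpp")]]
NumericVector gbt_margin_cpp(List trees, double base_margin, double eta,
                             NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += eta * tree_predict(tm, X, i);
  }
  return out;
}
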