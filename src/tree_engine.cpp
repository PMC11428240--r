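// Internal tree engine: exact-greedy CART regression trees, combined either
// by gradient boosting (squared loss, second-order leaf weights with L1/L2
// regularization) or by bootstrap averaging (random forest), plus the
// polynomial-time path-dependent TreeSHAP algorithm over the fitted trees.
//
// Trees are stored flat (0-based child indices, -1 feature marks a leaf).
// Leaf values are pre-scaled (by the learning rate for boosting, by 1/n_trees
// for forests) so a prediction is always base_score + sum over trees.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <random>

using namespace Rcpp;

struct Tree {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
  std::vector<double> cover;
};

struct BuildParams {
  int max_depth;
  int min_split;
  int min_leaf;
  double alpha;   // L1 on leaf weights
  double lambda;  // L2 on leaf weights
  int k_features; // features sampled per split; 0 = all
  double scale;   // multiplier applied to leaf values
};

static inline double soft_G(double G, double alpha) {
  double a = std::fabs(G) - alpha;
  return (a <= 0.0) ? 0.0 : std::copysign(a, G);
}

static inline double leaf_weight(double G, double H, const BuildParams& P) {
  double g = soft_G(G, P.alpha);
  return (g == 0.0) ? 0.0 : -g / (H + P.lambda);
}

static inline double split_score(double G, double H, const BuildParams& P) {
  double g = soft_G(G, P.alpha);
  return (g == 0.0) ? 0.0 : g * g / (H + P.lambda);
}

// Fisher-Yates front sample of k entries (without replacement)
static void sample_front(std::vector<int>& v, int k, std::mt19937& rng) {
  int n = (int)v.size();
  for (int i = 0; i < k && i < n - 1; ++i) {
    std::uniform_int_distribution<int> d(i, n - 1);
    std::swap(v[i], v[d(rng)]);
  }
}

static int build_node(Tree& tr, const NumericMatrix& X,
                      const std::vector<double>& g,
                      const std::vector<double>& h,
                      std::vector<int>& idx, int begin, int end, int depth,
                      const BuildParams& P, std::mt19937& rng) {
  int n = end - begin;
  double G = 0.0, H = 0.0;
  for (int i = begin; i < end; ++i) { G += g[idx[i]]; H += h[idx[i]]; }

  int node = (int)tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.value.push_back(P.scale * leaf_weight(G, H, P));
  tr.cover.push_back((double)n);

  if (depth >= P.max_depth || n < P.min_split || n < 2 * P.min_leaf)
    return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int k = (P.k_features > 0 && P.k_features < p) ? P.k_features : p;
  if (k < p) { sample_front(feats, k, rng); feats.resize(k); }

  double parent_score = split_score(G, H, P);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx.begin() + begin, idx.begin() + end);

  for (int fi = 0; fi < (int)feats.size(); ++fi) {
    int f = feats[fi];
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, f) < X(b, f); });
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      GL += g[ord[i]]; HL += h[ord[i]];
      if (X(ord[i], f) == X(ord[i + 1], f)) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < P.min_leaf || nr < P.min_leaf) continue;
      double gain = split_score(GL, HL, P) +
        split_score(G - GL, H - HL, P) - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
      }
    }
  }
  if (best_f < 0) return node;

  auto mid_it = std::stable_partition(
    idx.begin() + begin, idx.begin() + end,
    [&](int a) { return X(a, best_f) <= best_thr; });
  int mid = (int)(mid_it - idx.begin());
  if (mid == begin || mid == end) return node;  // degenerate split guard

  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  int L = build_node(tr, X, g, h, idx, begin, mid, depth + 1, P, rng);
  int R = build_node(tr, X, g, h, idx, mid, end, depth + 1, P, rng);
  tr.left[node] = L;
  tr.right[node] = R;
  return node;
}

static double predict_tree(const Tree& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    node = (X(row, tr.feature[node]) <= tr.threshold[node]) ?
      tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

static List tree_to_list(const Tree& tr) {
  return List::create(
    _["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
    _["threshold"] = NumericVector(tr.threshold.begin(), tr.threshold.end()),
    _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
    _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
    _["value"] = NumericVector(tr.value.begin(), tr.value.end()),
    _["cover"] = NumericVector(tr.cover.begin(), tr.cover.end()));
}

static Tree tree_from_list(const List& li) {
  Tree tr;
  IntegerVector f = li["feature"], l = li["left"], r = li["right"];
  NumericVector t = li["threshold"], v = li["value"], c = li["cover"];
  tr.feature.assign(f.begin(), f.end());
  tr.threshold.assign(t.begin(), t.end());
  tr.left.assign(l.begin(), l.end());
  tr.right.assign(r.begin(), r.end());
  tr.value.assign(v.begin(), v.end());
  tr.cover.assign(c.begin(), c.end());
  return tr;
}

// mode: "gbt" (stagewise boosting on residuals) or "rf" (bootstrap averaged)
// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, std::string mode,
                    int n_trees, double learning_rate, int max_depth,
                    int min_split, int min_leaf, double subsample,
                    int k_features, double reg_alpha, double reg_lambda,
                    int seed) {
  int n = X.nrow();
  if (n < 2) stop("need at least 2 rows");
  bool rf = (mode == "rf");
  std::mt19937 rng((unsigned)seed);

  double base = 0.0;
  std::vector<double> pred(n, 0.0);
  if (!rf) {
    for (int i = 0; i < n; ++i) base += y[i];
    base /= n;
    std::fill(pred.begin(), pred.end(), base);
  }

  BuildParams P;
  P.max_depth = max_depth;
  P.min_split = std::max(2, min_split);
  P.min_leaf = std::max(1, min_leaf);
  P.alpha = rf ? 0.0 : reg_alpha;
  P.lambda = rf ? 0.0 : reg_lambda;
  P.k_features = k_features;
  P.scale = rf ? 1.0 / n_trees : learning_rate;

  List trees(n_trees);
  std::vector<double> g(n), h(n, 1.0);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    if (rf) {
      idx.resize(n);
      std::uniform_int_distribution<int> d(0, n - 1);
      for (int i = 0; i < n; ++i) idx[i] = d(rng);
      for (int i = 0; i < n; ++i) g[i] = -y[i];
    } else {
      int m = std::max(2 * P.min_leaf,
                       (int)std::floor(subsample * n + 1e-9));
      m = std::min(m, n);
      idx = all;
      sample_front(idx, m, rng);
      idx.resize(m);
      for (int i = 0; i < n; ++i) g[i] = pred[i] - y[i];
    }
    Tree tr;
    build_node(tr, X, g, h, idx, 0, (int)idx.size(), 0, P, rng);
    if (!rf) {
      for (int i = 0; i < n; ++i) pred[i] += predict_tree(tr, X, i);
    }
    trees[t] = tree_to_list(tr);
  }
  return List::create(_["trees"] = trees, _["base"] = base,
                      _["mode"] = mode, _["n_features"] = X.ncol());
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List model, NumericMatrix X) {
  List trees = model["trees"];
  double base = as<double>(model["base"]);
  int n = X.nrow();
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tr, X, i);
  }
  return out;
}

// cover-weighted mean of leaf values (the tree's expected output over its
// own training sample)
static double tree_expected(const Tree& tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  double cl = tr.cover[tr.left[node]], cr = tr.cover[tr.right[node]];
  return (cl * tree_expected(tr, tr.left[node]) +
          cr * tree_expected(tr, tr.right[node])) / (cl + cr);
}

// [[Rcpp::export]]
double cpp_expected_value(List model) {
  List trees = model["trees"];
  double base = as<double>(model["base"]);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    base += tree_expected(tr, 0);
  }
  return base;
}

// ------------------------- TreeSHAP ---------------------------------------
// Path-dependent TreeSHAP: for each decision path the algorithm maintains
// the set of unique features on the path together with the fraction of
// "one" (feature follows x) and "zero" (feature marginalized by cover)
// paths, and the permutation weights, updated incrementally.

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement>& path, int unique_depth,
                        double pz, double po, int pi) {
  path[unique_depth].feature_index = pi;
  path[unique_depth].zero_fraction = pz;
  path[unique_depth].one_fraction = po;
  path[unique_depth].pweight = (unique_depth == 0) ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += po * path[i].pweight * (i + 1) /
      (double)(unique_depth + 1);
    path[i].pweight = pz * path[i].pweight * (unique_depth - i) /
      (double)(unique_depth + 1);
  }
}

static void unwind_path(std::vector<PathElement>& path, int unique_depth,
                        int path_index) {
  double po = path[path_index].one_fraction;
  double pz = path[path_index].zero_fraction;
  double next_one = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (po != 0.0) {
      double tmp = path[i].pweight;
      path[i].pweight = next_one * (unique_depth + 1) /
        (double)((i + 1) * po);
      next_one = tmp - path[i].pweight * pz * (unique_depth - i) /
        (double)(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
        (pz * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement>& path,
                               int unique_depth, int path_index) {
  double po = path[path_index].one_fraction;
  double pz = path[path_index].zero_fraction;
  double next_one = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (po != 0.0) {
      double tmp = next_one * (unique_depth + 1) / (double)((i + 1) * po);
      total += tmp;
      next_one = path[i].pweight - tmp * pz * (unique_depth - i) /
        (double)(unique_depth + 1);
    } else {
      total += (path[i].pweight / pz) * (unique_depth + 1) /
        (double)(unique_depth - i);
    }
  }
  return total;
}

static void shap_recurse(const Tree& tr, const double* x, double* phi,
                         int node, std::vector<PathElement> path,
                         int unique_depth, double parent_zero,
                         double parent_one, int parent_feature) {
  extend_path(path, unique_depth, parent_zero, parent_one, parent_feature);
  int f = tr.feature[node];
  if (f < 0) {
    for (int i = 1; i <= unique_depth; ++i) {
      double w = unwound_path_sum(path, unique_depth, i);
      const PathElement& el = path[i];
      phi[el.feature_index] +=
        w * (el.one_fraction - el.zero_fraction) * tr.value[node];
    }
    return;
  }
  int hot = (x[f] <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  double w = tr.cover[node];
  double hot_zero = tr.cover[hot] / w;
  double cold_zero = tr.cover[cold] / w;
  double incoming_zero = 1.0, incoming_one = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (path[path_index].feature_index == f) break;
  if (path_index != unique_depth + 1) {
    incoming_zero = path[path_index].zero_fraction;
    incoming_one = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  shap_recurse(tr, x, phi, hot, path, unique_depth + 1,
               hot_zero * incoming_zero, incoming_one, f);
  shap_recurse(tr, x, phi, cold, path, unique_depth + 1,
               cold_zero * incoming_zero, 0.0, f);
}

static int tree_depth(const Tree& tr, int node) {
  if (tr.feature[node] < 0) return 0;
  return 1 + std::max(tree_depth(tr, tr.left[node]),
                      tree_depth(tr, tr.right[node]));
}

// [[Rcpp::export]]
NumericMatrix cpp_tree_shap(List model, NumericMatrix X) {
  List trees = model["trees"];
  int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  std::vector<double> xrow(p);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    int maxd = tree_depth(tr, 0);
    std::vector<PathElement> path(maxd + 2);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::vector<double> ph(p, 0.0);
      shap_recurse(tr, xrow.data(), ph.data(), 0, path, 0, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += ph[j];
    }
  }
  return phi;
}
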