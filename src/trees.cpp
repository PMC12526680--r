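// CART-style tree learners: classification trees (gini, optionally with
// extra-trees random thresholds) bagged into forests, and second-order
// gradient-boosted regression trees with a softmax objective.
// No tree package ships with the target environment, so the primitives are
// implemented here.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct ClsTree {
  std::vector<int> feature;        // -1 => leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<std::vector<double>> prob;  // per-node class distribution
};

struct RegTree {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

struct ClsParams {
  int n_classes, mtry, max_depth, min_samples_split;
  bool random_splits;
};

double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double ss = 0.0;
  for (double c : cnt) ss += c * c;
  return 1.0 - ss / (n * n);
}

int grow_cls(const NumericMatrix& X, const IntegerVector& y,
             std::vector<int>& idx, int lo, int hi, int depth,
             const ClsParams& par, std::mt19937& rng, ClsTree& tree) {
  const int m = hi - lo;
  const int p = X.ncol();
  std::vector<double> cnt(par.n_classes, 0.0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]] += 1.0;

  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  std::vector<double> prob(par.n_classes);
  for (int c = 0; c < par.n_classes; ++c) prob[c] = cnt[c] / m;
  tree.prob.push_back(prob);

  bool pure = false;
  for (int c = 0; c < par.n_classes; ++c)
    if (cnt[c] == (double)m) { pure = true; break; }
  if (pure || m < par.min_samples_split || depth >= par.max_depth)
    return node;

  // candidate features: mtry distinct, seeded shuffle
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  for (int f = p - 1; f > 0; --f) {
    std::uniform_int_distribution<int> d(0, f);
    std::swap(feats[f], feats[d(rng)]);
  }

  double parent_imp = gini_from_counts(cnt, m);
  double best_score = parent_imp - 1e-12;  // require strict improvement
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(m);
  for (int fi = 0; fi < par.mtry && fi < p; ++fi) {
    int f = feats[fi];
    double fmin = R_PosInf, fmax = R_NegInf;
    for (int i = lo; i < hi; ++i) {
      double v = X(idx[i], f);
      if (v < fmin) fmin = v;
      if (v > fmax) fmax = v;
    }
    if (fmax <= fmin) continue;

    if (par.random_splits) {
      std::uniform_real_distribution<double> d(fmin, fmax);
      double thr = d(rng);
      std::vector<double> cl(par.n_classes, 0.0);
      double nl = 0.0;
      for (int i = lo; i < hi; ++i) {
        if (X(idx[i], f) <= thr) { cl[y[idx[i]]] += 1.0; nl += 1.0; }
      }
      if (nl == 0.0 || nl == (double)m) continue;
      double nr = m - nl;
      std::vector<double> cr(par.n_classes);
      for (int c = 0; c < par.n_classes; ++c) cr[c] = cnt[c] - cl[c];
      double score = (nl * gini_from_counts(cl, nl) +
                      nr * gini_from_counts(cr, nr)) / m;
      if (score < best_score) { best_score = score; best_f = f; best_thr = thr; }
    } else {
      for (int i = lo; i < hi; ++i)
        vals[i - lo] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      std::vector<double> cl(par.n_classes, 0.0);
      double ssl = 0.0;                  // sum of squared left counts
      double ssr = 0.0;
      for (int c = 0; c < par.n_classes; ++c) ssr += cnt[c] * cnt[c];
      for (int i = 0; i < m - 1; ++i) {
        int c = vals[i].second;
        ssl += 2.0 * cl[c] + 1.0;        // (cl+1)^2 - cl^2
        double r = cnt[c] - cl[c];
        ssr += -2.0 * r + 1.0;           // (r-1)^2 - r^2
        cl[c] += 1.0;
        if (vals[i + 1].first <= vals[i].first) continue;
        double nl = i + 1.0, nr = m - nl;
        double score = (nl * (1.0 - ssl / (nl * nl)) +
                        nr * (1.0 - ssr / (nr * nr))) / m;
        if (score < best_score) {
          best_score = score; best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
      // restore ssr base for next feature is unnecessary: recomputed above
    }
  }

  if (best_f < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int l = grow_cls(X, y, idx, lo, mid, depth + 1, par, rng, tree);
  int r = grow_cls(X, y, idx, mid, hi, depth + 1, par, rng, tree);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

int tree_leaf(const std::vector<int>& feature,
              const std::vector<double>& threshold,
              const std::vector<int>& left, const std::vector<int>& right,
              const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return node;
}

List cls_tree_to_list(const ClsTree& t, int n_classes) {
  int nn = (int)t.feature.size();
  NumericMatrix prob(nn, n_classes);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < n_classes; ++c) prob(i, c) = t.prob[i][c];
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["prob"] = prob);
}

struct RegParams {
  int max_depth, min_samples_split;
  double reg_lambda;
};

int grow_reg(const NumericMatrix& X, const std::vector<double>& g,
             const std::vector<double>& h, std::vector<int>& idx,
             int lo, int hi, int depth, const RegParams& par, RegTree& tree) {
  const int m = hi - lo;
  const int p = X.ncol();
  double G = 0.0, H = 0.0;
  for (int i = lo; i < hi; ++i) { G += g[idx[i]]; H += h[idx[i]]; }

  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(-G / (H + par.reg_lambda));

  if (m < par.min_samples_split || depth >= par.max_depth) return node;

  double parent_gain = G * G / (H + par.reg_lambda);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(m);
  for (int f = 0; f < p; ++f) {
    for (int i = lo; i < hi; ++i) vals[i - lo] = {X(idx[i], f), idx[i]};
    std::sort(vals.begin(), vals.end());
    if (vals[m - 1].first <= vals[0].first) continue;
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      GL += g[vals[i].second];
      HL += h[vals[i].second];
      if (vals[i + 1].first <= vals[i].first) continue;
      double GR = G - GL, HR = H - HL;
      double gain = GL * GL / (HL + par.reg_lambda) +
                    GR * GR / (HR + par.reg_lambda) - parent_gain;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }

  if (best_f < 0) return node;
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int l = grow_reg(X, g, h, idx, lo, mid, depth + 1, par, tree);
  int r = grow_reg(X, g, h, idx, mid, hi, depth + 1, par, tree);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, IntegerVector y, int n_classes,
                    int n_trees, int mtry, int max_depth,
                    int min_samples_split, bool bootstrap, bool random_splits,
                    int seed) {
  const int n = X.nrow();
  ClsParams par{n_classes, mtry, max_depth, min_samples_split, random_splits};
  std::mt19937 rng((unsigned)seed);
  List forest(n_trees);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    ClsTree tree;
    grow_cls(X, y, idx, 0, n, 0, par, rng, tree);
    forest[b] = cls_tree_to_list(tree, n_classes);
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix cpp_forest_proba(List forest, NumericMatrix X, int n_classes) {
  const int n = X.nrow();
  const int B = forest.size();
  NumericMatrix out(n, n_classes);
  for (int b = 0; b < B; ++b) {
    List t = forest[b];
    std::vector<int> feature = as<std::vector<int>>(t["feature"]);
    std::vector<double> threshold = as<std::vector<double>>(t["threshold"]);
    std::vector<int> left = as<std::vector<int>>(t["left"]);
    std::vector<int> right = as<std::vector<int>>(t["right"]);
    NumericMatrix prob = t["prob"];
    for (int i = 0; i < n; ++i) {
      int leaf = tree_leaf(feature, threshold, left, right, X, i);
      for (int c = 0; c < n_classes; ++c) out(i, c) += prob(leaf, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < n_classes; ++c) out(i, c) /= B;
  return out;
}

// [[Rcpp::export]]
List cpp_fit_gbt(NumericMatrix X, IntegerVector y, int n_classes,
                 int n_rounds, double learning_rate, int max_depth,
                 int min_samples_split, double subsample, double reg_lambda,
                 int seed) {
  const int n = X.nrow();
  RegParams par{max_depth, min_samples_split, reg_lambda};
  std::mt19937 rng((unsigned)seed);
  std::vector<double> F(n * n_classes, 0.0);  // margins, column-major
  std::vector<double> P(n * n_classes, 0.0);
  List rounds(n_rounds);
  int n_sub = std::max(2, (int)std::floor(subsample * n));

  for (int r = 0; r < n_rounds; ++r) {
    // softmax probabilities from current margins
    for (int i = 0; i < n; ++i) {
      double mx = F[i];
      for (int c = 1; c < n_classes; ++c) mx = std::max(mx, F[i + c * n]);
      double s = 0.0;
      for (int c = 0; c < n_classes; ++c) {
        P[i + c * n] = std::exp(F[i + c * n] - mx);
        s += P[i + c * n];
      }
      for (int c = 0; c < n_classes; ++c) P[i + c * n] /= s;
    }
    // row subsample for this round (without replacement)
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    if (n_sub < n) {
      for (int i = 0; i < n_sub; ++i) {
        std::uniform_int_distribution<int> d(i, n - 1);
        std::swap(rows[i], rows[d(rng)]);
      }
      rows.resize(n_sub);
    }

    List trees(n_classes);
    std::vector<double> g(n), h(n);
    for (int c = 0; c < n_classes; ++c) {
      for (int i = 0; i < n; ++i) {
        double p = P[i + c * n];
        g[i] = p - (y[i] == c ? 1.0 : 0.0);
        h[i] = std::max(p * (1.0 - p), 1e-12);
      }
      RegTree tree;
      std::vector<int> idx(rows);
      grow_reg(X, g, h, idx, 0, (int)idx.size(), 0, par, tree);
      // scale leaf values by the learning rate once, at fit time
      for (size_t k = 0; k < tree.value.size(); ++k)
        tree.value[k] *= learning_rate;
      // update margins for ALL rows
      for (int i = 0; i < n; ++i) {
        int leaf = tree_leaf(tree.feature, tree.threshold, tree.left,
                             tree.right, X, i);
        F[i + c * n] += tree.value[leaf];
      }
      trees[c] = List::create(_["feature"] = wrap(tree.feature),
                              _["threshold"] = wrap(tree.threshold),
                              _["left"] = wrap(tree.left),
                              _["right"] = wrap(tree.right),
                              _["value"] = wrap(tree.value));
    }
    rounds[r] = trees;
  }
  return rounds;
}

// [[Rcpp::export]]
NumericMatrix cpp_gbt_proba(List rounds, NumericMatrix X, int n_classes) {
  const int n = X.nrow();
  NumericMatrix F(n, n_classes);
  for (int r = 0; r < rounds.size(); ++r) {
    List trees = rounds[r];
    for (int c = 0; c < n_classes; ++c) {
      List t = trees[c];
      std::vector<int> feature = as<std::vector<int>>(t["feature"]);
      std::vector<double> threshold = as<std::vector<double>>(t["threshold"]);
      std::vector<int> left = as<std::vector<int>>(t["left"]);
      std::vector<int> right = as<std::vector<int>>(t["right"]);
      std::vector<double> value = as<std::vector<double>>(t["value"]);
      for (int i = 0; i < n; ++i) {
        int leaf = tree_leaf(feature, threshold, left, right, X, i);
        F(i, c) += value[leaf];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    double mx = F(i, 0);
    for (int c = 1; c < n_classes; ++c) mx = std::max(mx, F(i, c));
    double s = 0.0;
    for (int c = 0; c < n_classes; ++c) { F(i, c) = std::exp(F(i, c) - mx); s += F(i, c); }
    for (int c = 0; c < n_classes; ++c) F(i, c) /= s;
  }
  return F;
}
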