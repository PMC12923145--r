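#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// A single CART engine (second-order gradient statistics, exact greedy
// splits) shared by six classifier variants assembled on the R side:
//   - GBDT:     first-order boosting (h = 1), depth-wise growth
//   - XGBoost:  second-order boosting, depth-wise growth, L2 penalty
//   - LightGBM: second-order boosting, leaf-wise (best-first) growth
//   - CatBoost: second-order boosting, oblivious (symmetric) trees
//   - AdaBoost: SAMME with weighted CART stumps/trees
//   - RF:       bootstrap-aggregated probability trees with per-node mtry
// Trees are flat parallel arrays; split rule is x[f] < thr -> left.

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> thr, value, cover;
  int add_node() {
    feature.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    value.push_back(0.0); cover.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

static List tree_to_list(const Tree& t) {
  return List::create(
    _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
    _["thr"] = NumericVector(t.thr.begin(), t.thr.end()),
    _["left"] = IntegerVector(t.left.begin(), t.left.end()),
    _["right"] = IntegerVector(t.right.begin(), t.right.end()),
    _["value"] = NumericVector(t.value.begin(), t.value.end()),
    _["cover"] = NumericVector(t.cover.begin(), t.cover.end()));
}

struct SplitInfo {
  double gain = -1.0, thr = 0.0;
  int feat = -1;
};

static inline double leaf_weight(double G, double H, double lambda) {
  double den = H + lambda;
  return (den <= 1e-12) ? 0.0 : -G / den;
}

static SplitInfo best_split(const NumericMatrix& X, const std::vector<int>& rows,
                            const std::vector<double>& g, const std::vector<double>& h,
                            double lambda, int min_child, const std::vector<int>& feats) {
  SplitInfo best;
  int n = (int)rows.size();
  if (n < 2 * min_child) return best;
  double G = 0, H = 0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  double parent = G * G / (H + lambda);
  const double* Xp = X.begin();
  const size_t nrow = X.nrow();
  std::vector<std::pair<double, int>> v(n);
  for (int f : feats) {
    const double* col = Xp + (size_t)f * nrow;
    for (int i = 0; i < n; ++i) v[i] = {col[rows[i]], rows[i]};
    std::sort(v.begin(), v.end());
    if (v.front().first == v.back().first) continue;
    double GL = 0, HL = 0;
    for (int i = 0; i < n - 1; ++i) {
      GL += g[v[i].second]; HL += h[v[i].second];
      if (v[i].first == v[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_child || nr < min_child) continue;
      double GR = G - GL, HR = H - HL;
      double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent;
      if (gain > best.gain + 1e-12) {
        best.gain = gain; best.feat = f;
        best.thr = 0.5 * (v[i].first + v[i + 1].first);
      }
    }
  }
  return best;
}

static std::vector<int> sample_feats(int p, int mtry, std::mt19937& rng) {
  std::vector<int> all(p);
  for (int i = 0; i < p; ++i) all[i] = i;
  if (mtry <= 0 || mtry >= p) return all;
  std::shuffle(all.begin(), all.end(), rng);
  all.resize(mtry);
  std::sort(all.begin(), all.end());
  return all;
}

struct GrowJob { int node, depth; std::vector<int> rows; };

// depth-wise growth; mtry > 0 resamples features per node (random forest)
static Tree grow_depthwise(const NumericMatrix& X, const std::vector<int>& rows0,
                           const std::vector<double>& g, const std::vector<double>& h,
                           int max_depth, int min_child, double lambda,
                           const std::vector<int>& feats, int mtry, std::mt19937& rng) {
  Tree t;
  int root = t.add_node();
  std::vector<GrowJob> stack{{root, 0, rows0}};
  int p = X.ncol();
  while (!stack.empty()) {
    GrowJob job = std::move(stack.back());
    stack.pop_back();
    double G = 0, H = 0;
    for (int r : job.rows) { G += g[r]; H += h[r]; }
    t.value[job.node] = leaf_weight(G, H, lambda);
    t.cover[job.node] = (double)job.rows.size();
    if (job.depth >= max_depth) continue;
    std::vector<int> fs = (mtry > 0) ? sample_feats(p, mtry, rng) : feats;
    SplitInfo s = best_split(X, job.rows, g, h, lambda, min_child, fs);
    if (s.feat < 0 || s.gain <= 1e-12) continue;
    std::vector<int> lr, rr;
    for (int r : job.rows) (X(r, s.feat) < s.thr ? lr : rr).push_back(r);
    if (lr.empty() || rr.empty()) continue;
    int nl = t.add_node(), nr = t.add_node();
    t.feature[job.node] = s.feat; t.thr[job.node] = s.thr;
    t.left[job.node] = nl; t.right[job.node] = nr;
    stack.push_back({nl, job.depth + 1, std::move(lr)});
    stack.push_back({nr, job.depth + 1, std::move(rr)});
  }
  return t;
}

// leaf-wise (best-first) growth up to max_leaves
static Tree grow_leafwise(const NumericMatrix& X, const std::vector<int>& rows0,
                          const std::vector<double>& g, const std::vector<double>& h,
                          int max_leaves, int max_depth, int min_child, double lambda,
                          const std::vector<int>& feats) {
  Tree t;
  int root = t.add_node();
  struct Cand { int node, depth; std::vector<int> rows; SplitInfo s; };
  std::vector<Cand> leaves;
  auto init_node = [&](int node, int depth, std::vector<int> rows) {
    double G = 0, H = 0;
    for (int r : rows) { G += g[r]; H += h[r]; }
    t.value[node] = leaf_weight(G, H, lambda);
    t.cover[node] = (double)rows.size();
    SplitInfo s;
    if (depth < max_depth) s = best_split(X, rows, g, h, lambda, min_child, feats);
    leaves.push_back({node, depth, std::move(rows), s});
  };
  init_node(root, 0, rows0);
  int n_leaves = 1;
  while (n_leaves < max_leaves) {
    int bi = -1;
    double bg = 1e-12;
    for (size_t i = 0; i < leaves.size(); ++i)
      if (leaves[i].s.feat >= 0 && leaves[i].s.gain > bg) { bg = leaves[i].s.gain; bi = (int)i; }
    if (bi < 0) break;
    Cand c = std::move(leaves[bi]);
    leaves.erase(leaves.begin() + bi);
    std::vector<int> lr, rr;
    for (int r : c.rows) (X(r, c.s.feat) < c.s.thr ? lr : rr).push_back(r);
    if (lr.empty() || rr.empty()) continue;
    int nl = t.add_node(), nr = t.add_node();
    t.feature[c.node] = c.s.feat; t.thr[c.node] = c.s.thr;
    t.left[c.node] = nl; t.right[c.node] = nr;
    init_node(nl, c.depth + 1, std::move(lr));
    init_node(nr, c.depth + 1, std::move(rr));
    ++n_leaves;
  }
  return t;
}

// oblivious (symmetric) growth: one shared (feature, threshold) per level,
// chosen to maximise total gain over all level nodes; candidate thresholds
// are up to 32 root-level quantile midpoints per feature
static Tree grow_oblivious(const NumericMatrix& X, const std::vector<int>& rows0,
                           const std::vector<double>& g, const std::vector<double>& h,
                           int max_depth, int min_child, double lambda,
                           const std::vector<int>& feats) {
  Tree t;
  int root = t.add_node();
  struct LevNode { int node; std::vector<int> rows; };
  std::vector<LevNode> level{{root, rows0}};
  {
    double G = 0, H = 0;
    for (int r : rows0) { G += g[r]; H += h[r]; }
    t.value[root] = leaf_weight(G, H, lambda);
    t.cover[root] = (double)rows0.size();
  }
  // candidate thresholds per feature from root rows
  int p = X.ncol();
  std::vector<std::vector<double>> cand(p);
  for (int f : feats) {
    std::vector<double> v;
    v.reserve(rows0.size());
    for (int r : rows0) v.push_back(X(r, f));
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    if (v.size() < 2) continue;
    int nuq = (int)v.size();
    int nth = std::min(31, nuq - 1);
    for (int k = 1; k <= nth; ++k) {
      int idx = (int)std::floor((double)k * nuq / (nth + 1));
      idx = std::max(1, std::min(idx, nuq - 1));
      cand[f].push_back(0.5 * (v[idx - 1] + v[idx]));
    }
    std::sort(cand[f].begin(), cand[f].end());
    cand[f].erase(std::unique(cand[f].begin(), cand[f].end()), cand[f].end());
  }

  for (int depth = 0; depth < max_depth; ++depth) {
    double best_gain = 1e-12, best_thr = 0;
    int best_f = -1;
    for (int f : feats) {
      const std::vector<double>& th = cand[f];
      if (th.empty()) continue;
      // per node, per threshold-bin gradient sums; bin(x) = #thresholds <= x,
      // so the left side of th[j] is the prefix of bins 0..j
      std::vector<double> gain_at(th.size(), 0.0);
      for (auto& ln : level) {
        if (ln.rows.empty()) continue;
        std::vector<double> Gb(th.size() + 1, 0.0), Hb(th.size() + 1, 0.0);
        for (int r : ln.rows) {
          int b = (int)(std::upper_bound(th.begin(), th.end(), X(r, f)) - th.begin());
          Gb[b] += g[r]; Hb[b] += h[r];
        }
        double G = 0, H = 0;
        for (size_t b = 0; b < Gb.size(); ++b) { G += Gb[b]; H += Hb[b]; }
        double parent = G * G / (H + lambda);
        double GL = 0, HL = 0;
        for (size_t b = 0; b + 1 < Gb.size(); ++b) {
          GL += Gb[b]; HL += Hb[b];
          double GR = G - GL, HR = H - HL;
          gain_at[b] += GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent;
        }
      }
      for (size_t b = 0; b < gain_at.size(); ++b)
        if (gain_at[b] > best_gain) { best_gain = gain_at[b]; best_f = f; best_thr = th[b]; }
    }
    if (best_f < 0) break;
    std::vector<LevNode> next;
    for (auto& ln : level) {
      if (ln.rows.empty()) continue;  // empty level nodes stay leaves
      std::vector<int> lr, rr;
      for (int r : ln.rows) (X(r, best_f) < best_thr ? lr : rr).push_back(r);
      if (lr.empty() || rr.empty()) { next.push_back(std::move(ln)); continue; }
      int nl = t.add_node(), nr = t.add_node();
      t.feature[ln.node] = best_f; t.thr[ln.node] = best_thr;
      t.left[ln.node] = nl; t.right[ln.node] = nr;
      auto fill = [&](int node, const std::vector<int>& rows) {
        double G = 0, H = 0;
        for (int r : rows) { G += g[r]; H += h[r]; }
        t.value[node] = leaf_weight(G, H, lambda);
        t.cover[node] = (double)rows.size();
      };
      fill(nl, lr); fill(nr, rr);
      next.push_back({nl, std::move(lr)});
      next.push_back({nr, std::move(rr)});
    }
    level = std::move(next);
  }
  return t;
}

static double predict_tree(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) < t.thr[node]) ? t.left[node] : t.right[node];
  return t.value[node];
}

static Tree tree_from_list(List tl) {
  Tree t;
  IntegerVector f = tl["feature"], l = tl["left"], r = tl["right"];
  NumericVector th = tl["thr"], v = tl["value"], c = tl["cover"];
  t.feature.assign(f.begin(), f.end());
  t.left.assign(l.begin(), l.end());
  t.right.assign(r.begin(), r.end());
  t.thr.assign(th.begin(), th.end());
  t.value.assign(v.begin(), v.end());
  t.cover.assign(c.begin(), c.end());
  return t;
}

// gradient boosting (growth: 0 depth-wise, 1 leaf-wise, 2 oblivious;
// order: 1 first-order h=1, 2 logistic second-order)
// [[Rcpp::export]]
List cpp_boost(NumericMatrix X, NumericVector y, int n_trees, double learning_rate,
               int max_depth, int max_leaves, int growth, double lambda,
               double subsample, double colsample, int order, int min_child, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed * 2654435761u + 97u);
  double ybar = std::min(1.0 - 1e-6, std::max(1e-6, (double)mean(y)));
  double base = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, base), g(n), h(n);
  List trees(n_trees);
  int kept = 0;
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = pr - y[i];
      h[i] = (order == 2) ? std::max(pr * (1.0 - pr), 1e-6) : 1.0;
    }
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    if (subsample < 1.0) {
      std::shuffle(rows.begin(), rows.end(), rng);
      rows.resize(std::max(2, (int)std::floor(subsample * n)));
      std::sort(rows.begin(), rows.end());
    }
    std::vector<int> feats(p);
    for (int i = 0; i < p; ++i) feats[i] = i;
    if (colsample < 1.0) {
      std::shuffle(feats.begin(), feats.end(), rng);
      feats.resize(std::max(1, (int)std::floor(colsample * p)));
      std::sort(feats.begin(), feats.end());
    }
    Tree t;
    if (growth == 2) t = grow_oblivious(X, rows, g, h, max_depth, min_child, lambda, feats);
    else if (growth == 1) t = grow_leafwise(X, rows, g, h, max_leaves, std::max(max_depth, 16), min_child, lambda, feats);
    else t = grow_depthwise(X, rows, g, h, max_depth, min_child, lambda, feats, 0, rng);
    for (size_t k = 0; k < t.value.size(); ++k) t.value[k] *= learning_rate;
    for (int i = 0; i < n; ++i) F[i] += predict_tree(t, X, i);
    trees[m] = tree_to_list(t);
    ++kept;
  }
  return List::create(_["trees"] = trees, _["base"] = base, _["n_kept"] = kept);
}

// random forest of probability trees (leaf value = in-bag mean of y, scaled 1/T)
// [[Rcpp::export]]
List cpp_rf(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
            int min_child, int mtry, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed * 2654435761u + 13u);
  std::uniform_int_distribution<int> pick(0, n - 1);
  std::vector<double> g(n), h(n, 1.0);
  for (int i = 0; i < n; ++i) g[i] = -y[i];  // leaf value -G/H = mean(y)
  std::vector<int> feats(p);
  for (int i = 0; i < p; ++i) feats[i] = i;
  List trees(n_trees);
  for (int m = 0; m < n_trees; ++m) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = pick(rng);
    std::sort(rows.begin(), rows.end());
    Tree t = grow_depthwise(X, rows, g, h, max_depth, min_child, 0.0, feats,
                            std::max(1, mtry), rng);
    for (size_t k = 0; k < t.value.size(); ++k) t.value[k] /= (double)n_trees;
    trees[m] = tree_to_list(t);
  }
  return List::create(_["trees"] = trees, _["base"] = 0.0, _["n_kept"] = n_trees);
}

// SAMME AdaBoost with weighted CART weak learners; margin F(x) = sum alpha_m h_m(x),
// h_m in {-1,+1}; leaf values store lr * alpha * sign so the ensemble is additive
// [[Rcpp::export]]
List cpp_adaboost(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
                  double learning_rate, int min_child, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed * 2654435761u + 29u);
  std::vector<double> w(n, 1.0 / n), yc(n), g(n), h(n);
  for (int i = 0; i < n; ++i) yc[i] = (y[i] > 0.5) ? 1.0 : -1.0;
  std::vector<int> rows(n), feats(p);
  for (int i = 0; i < n; ++i) rows[i] = i;
  for (int i = 0; i < p; ++i) feats[i] = i;
  List trees(n_trees);
  int kept = 0;
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) { g[i] = -w[i] * yc[i]; h[i] = w[i]; }
    Tree t = grow_depthwise(X, rows, g, h, max_depth, min_child, 0.0, feats, 0, rng);
    // weighted error of the sign classifier
    double err = 0, wsum = 0;
    std::vector<double> pred(n);
    for (int i = 0; i < n; ++i) {
      pred[i] = (predict_tree(t, X, i) >= 0) ? 1.0 : -1.0;
      wsum += w[i];
      if (pred[i] != yc[i]) err += w[i];
    }
    err /= wsum;
    if (err >= 0.5 - 1e-10) break;  // no usable weak learner left
    double alpha = 0.5 * std::log((1.0 - err) / std::max(err, 1e-10));
    alpha = std::min(alpha, 10.0);
    for (size_t k = 0; k < t.value.size(); ++k)
      t.value[k] = learning_rate * alpha * ((t.value[k] >= 0) ? 1.0 : -1.0);
    for (int i = 0; i < n; ++i) w[i] *= std::exp(-learning_rate * alpha * yc[i] * pred[i]);
    double s = 0;
    for (int i = 0; i < n; ++i) s += w[i];
    for (int i = 0; i < n; ++i) w[i] /= s;
    trees[kept++] = tree_to_list(t);
    if (err <= 1e-10) break;  // perfect weak learner
  }
  if (kept < n_trees) {
    List kl(kept);
    for (int i = 0; i < kept; ++i) kl[i] = trees[i];
    trees = kl;
  }
  return List::create(_["trees"] = trees, _["base"] = 0.0, _["n_kept"] = kept);
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, double base, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n, base);
  for (int m = 0; m < trees.size(); ++m) {
    Tree t = tree_from_list(trees[m]);
    for (int i = 0; i < n; ++i) out[i] += predict_tree(t, X, i);
  }
  return out;
}
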