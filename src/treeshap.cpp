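#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Path-dependent TreeSHAP (polynomial-time Shapley values for tree
// ensembles). Follows the EXTEND/UNWIND formulation; conditional
// expectations use per-node training covers. Split rule matches the
// engine: x[f] < thr -> left. Verified in the test suite against a
// brute-force subset-enumeration Shapley oracle on small trees.

struct STree {
  std::vector<int> feature, left, right;
  std::vector<double> thr, value, cover;
};

struct PE { int d; double z, o, w; };

static void extend(std::vector<PE>& m, double pz, double po, int pi) {
  int l = (int)m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (double)(i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (double)(l - i) / (double)(l + 1);
  }
}

// sum of path weights after removing element j's (z,o) influence
static double unwound_sum(const std::vector<PE>& m, int j) {
  int l = (int)m.size() - 1;
  double o = m[j].o, z = m[j].z, total = 0.0;
  if (o != 0.0) {
    std::vector<double> old(l);
    old[l - 1] = m[l].w * (double)(l + 1) / (o * (double)l);
    for (int i = l - 1; i >= 1; --i)
      old[i - 1] = (m[i].w - z * old[i] * (double)(l - i) / (double)(l + 1)) *
                   (double)(l + 1) / (o * (double)i);
    for (double x : old) total += x;
  } else {
    for (int i = 0; i < l; ++i)
      total += (z == 0.0) ? 0.0 : m[i].w * (double)(l + 1) / (z * (double)(l - i));
  }
  return total;
}

static std::vector<PE> unwind(const std::vector<PE>& m, int j) {
  int l = (int)m.size() - 1;
  double o = m[j].o, z = m[j].z;
  std::vector<PE> out(m.begin(), m.end() - 1);
  if (o != 0.0) {
    std::vector<double> old(l);
    old[l - 1] = m[l].w * (double)(l + 1) / (o * (double)l);
    for (int i = l - 1; i >= 1; --i)
      old[i - 1] = (m[i].w - z * old[i] * (double)(l - i) / (double)(l + 1)) *
                   (double)(l + 1) / (o * (double)i);
    for (int i = 0; i < l; ++i) out[i].w = old[i];
  } else {
    for (int i = 0; i < l; ++i)
      out[i].w = (z == 0.0) ? 0.0 : m[i].w * (double)(l + 1) / (z * (double)(l - i));
  }
  for (int i = j; i < l; ++i) {
    out[i].d = m[i + 1].d;
    out[i].z = m[i + 1].z;
    out[i].o = m[i + 1].o;
  }
  return out;
}

static void shap_recurse(const STree& t, const NumericMatrix& X, int row,
                         std::vector<double>& phi, int node,
                         std::vector<PE> path, double pz, double po, int pd) {
  extend(path, pz, po, pd);
  int f = t.feature[node];
  if (f < 0) {  // leaf
    int l = (int)path.size() - 1;
    for (int j = 1; j <= l; ++j) {
      double w = unwound_sum(path, j);
      phi[path[j].d] += w * (path[j].o - path[j].z) * t.value[node];
    }
    return;
  }
  int hot = (X(row, f) < t.thr[node]) ? t.left[node] : t.right[node];
  int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)path.size(); ++i)
    if (path[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = path[k].z;
    io = path[k].o;
    path = unwind(path, k);
  }
  double cov = t.cover[node];
  if (cov <= 0) return;
  shap_recurse(t, X, row, phi, hot, path, iz * t.cover[hot] / cov, io, f);
  shap_recurse(t, X, row, phi, cold, path, iz * t.cover[cold] / cov, 0.0, f);
}

static STree stree_from_list(List tl) {
  STree t;
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

static double tree_expectation(const STree& t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  double cl = t.cover[t.left[node]], cr = t.cover[t.right[node]];
  double c = cl + cr;
  if (c <= 0) return t.value[node];
  return (tree_expectation(t, t.left[node]) * cl +
          tree_expectation(t, t.right[node]) * cr) / c;
}

// [[Rcpp::export]]
NumericMatrix cpp_treeshap(List trees, NumericMatrix X, int n_features) {
  int n = X.nrow();
  NumericMatrix phi(n, n_features);
  for (int m = 0; m < trees.size(); ++m) {
    STree t = stree_from_list(trees[m]);
    if (t.feature.empty()) continue;
    for (int i = 0; i < n; ++i) {
      std::vector<double> p(n_features, 0.0);
      std::vector<PE> path;
      shap_recurse(t, X, i, p, 0, path, 1.0, 1.0, -1);
      for (int j = 0; j < n_features; ++j) phi(i, j) += p[j];
    }
  }
  return phi;
}

// [[Rcpp::export]]
double cpp_forest_expectation(List trees) {
  double e = 0.0;
  for (int m = 0; m < trees.size(); ++m) {
    STree t = stree_from_list(trees[m]);
    if (!t.feature.empty()) e += tree_expectation(t, 0);
  }
  return e;
}
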