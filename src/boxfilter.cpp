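#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Separable sliding-window aggregates over 2D/3D arrays stored column-major
// (R array layout). Window along each axis spans offsets lo..hi inclusive;
// out-of-grid positions are edge-replicated. A symmetric box of radius r is
// lo=-r, hi=r; the 2x2(x2) anchor-at-minimum kernel is lo=0, hi=1.

enum AggOp { SUM = 0, MIN = 1, MAX = 2 };

static void axis_pass(const std::vector<double>& in, std::vector<double>& out,
                      const std::vector<int>& dim, int axis, int lo, int hi, int op) {
  int nd = dim.size();
  std::vector<int> stride(nd, 1);
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dim[d - 1];
  int n_axis = dim[axis], s = stride[axis];
  long total = 1;
  for (int d = 0; d < nd; ++d) total *= dim[d];
  long n_lines = total / n_axis;

  // enumerate lines: iterate all indices with axis coordinate fixed at 0
  std::vector<int> odim;
  std::vector<int> ostride;
  for (int d = 0; d < nd; ++d)
    if (d != axis) { odim.push_back(dim[d]); ostride.push_back(stride[d]); }

  std::vector<double> line(n_axis);
  for (long li = 0; li < n_lines; ++li) {
    long rem = li, base = 0;
    for (size_t d = 0; d < odim.size(); ++d) {
      base += (rem % odim[d]) * ostride[d];
      rem /= odim[d];
    }
    for (int i = 0; i < n_axis; ++i) line[i] = in[base + (long)i * s];
    for (int i = 0; i < n_axis; ++i) {
      double acc = (op == SUM) ? 0.0 : line[std::min(std::max(i + lo, 0), n_axis - 1)];
      for (int t = lo; t <= hi; ++t) {
        int j = std::min(std::max(i + t, 0), n_axis - 1);
        double v = line[j];
        if (op == SUM) acc += v;
        else if (op == MIN) acc = std::min(acc, v);
        else acc = std::max(acc, v);
      }
      out[base + (long)i * s] = acc;
    }
  }
}

static NumericVector window_agg(NumericVector a, IntegerVector dim, int lo, int hi, int op) {
  int nd = dim.size();
  std::vector<int> d(dim.begin(), dim.end());
  std::vector<double> cur(a.begin(), a.end()), nxt(a.size());
  for (int ax = 0; ax < nd; ++ax) {
    axis_pass(cur, nxt, d, ax, lo, hi, op);
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_window_sum(NumericVector a, IntegerVector dim, int lo, int hi) {
  return window_agg(a, dim, lo, hi, SUM);
}

// [[Rcpp::export]]
NumericVector cpp_window_min(NumericVector a, IntegerVector dim, int lo, int hi) {
  return window_agg(a, dim, lo, hi, MIN);
}

// [[Rcpp::export]]
NumericVector cpp_window_max(NumericVector a, IntegerVector dim, int lo, int hi) {
  return window_agg(a, dim, lo, hi, MAX);
}

// 1D separable filter response along one axis (edge-replicated), e.g. the
// smoothing [1,2,1], edge [-1,0,1] and spot [1,-2,1] taps.
// [[Rcpp::export]]
NumericVector cpp_axis_filter(NumericVector a, IntegerVector dim, int axis, NumericVector taps) {
  int nd = dim.size();
  std::vector<int> d(dim.begin(), dim.end());
  std::vector<int> stride(nd, 1);
  for (int k = 1; k < nd; ++k) stride[k] = stride[k - 1] * d[k - 1];
  int n_axis = d[axis], s = stride[axis];
  long total = a.size();
  long n_lines = total / n_axis;
  int half = (taps.size() - 1) / 2;

  std::vector<int> odim, ostride;
  for (int k = 0; k < nd; ++k)
    if (k != axis) { odim.push_back(d[k]); ostride.push_back(stride[k]); }

  NumericVector out(total);
  std::vector<double> line(n_axis);
  for (long li = 0; li < n_lines; ++li) {
    long rem = li, base = 0;
    for (size_t k = 0; k < odim.size(); ++k) {
      base += (rem % odim[k]) * ostride[k];
      rem /= odim[k];
    }
    for (int i = 0; i < n_axis; ++i) line[i] = a[base + (long)i * s];
    for (int i = 0; i < n_axis; ++i) {
      double acc = 0;
      for (int t = 0; t < taps.size(); ++t) {
        int j = std::min(std::max(i + t - half, 0), n_axis - 1);
        acc += taps[t] * line[j];
      }
      out[base + (long)i * s] = acc;
    }
  }
  out.attr("dim") = dim;
  return out;
}
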