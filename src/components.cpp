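#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of an integer cluster-label grid under full
// diagonal adjacency (8-connectivity in 2D, 26-connectivity in 3D) or
// face-only adjacency (4/6). Two elements are connected iff they carry the
// same nonzero cluster label and are adjacent under the chosen topology.
// Returns a grid of consecutive component ids (1..n_comp, 0 on background)
// with attribute "cluster" mapping each component id to its cluster label.

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector labels, IntegerVector dim, bool diagonal) {
  int nd = dim.size();
  if (nd != 2 && nd != 3) stop("only 2D/3D grids supported");
  int n1 = dim[0], n2 = dim[1], n3 = (nd == 3) ? dim[2] : 1;
  long total = (long)n1 * n2 * n3;

  // neighbor offsets
  std::vector<std::array<int, 3>> offs;
  int zlo = (nd == 3) ? -1 : 0, zhi = (nd == 3) ? 1 : 0;
  for (int dz = zlo; dz <= zhi; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (!diagonal && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  IntegerVector comp(total, 0);
  std::vector<int> comp_cluster;
  std::vector<long> stack;
  int next_id = 0;

  for (long start = 0; start < total; ++start) {
    if (labels[start] == 0 || comp[start] != 0) continue;
    int lab = labels[start];
    ++next_id;
    comp_cluster.push_back(lab);
    comp[start] = next_id;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      long cur = stack.back();
      stack.pop_back();
      int x = cur % n1, y = (cur / n1) % n2, z = cur / ((long)n1 * n2);
      for (auto& o : offs) {
        int nx = x + o[0], ny = y + o[1], nz = z + o[2];
        if (nx < 0 || nx >= n1 || ny < 0 || ny >= n2 || nz < 0 || nz >= n3) continue;
        long ni = nx + (long)ny * n1 + (long)nz * n1 * n2;
        if (labels[ni] == lab && comp[ni] == 0) {
          comp[ni] = next_id;
          stack.push_back(ni);
        }
      }
    }
  }
  comp.attr("dim") = dim;
  comp.attr("cluster") = IntegerVector(comp_cluster.begin(), comp_cluster.end());
  return comp;
}
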