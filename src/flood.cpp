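#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected flood fill over the fluid mask from a seed node; returns
// the reachable-fluid mask. Used to restrict the flow domain to the
// lumen's connected component (isolated interstices between cell disks
// are not part of the flow).
// [[Rcpp::export]]
LogicalMatrix flood_fill_cpp(LogicalMatrix solid, int si, int sj) {
  int nx = solid.nrow(), ny = solid.ncol();
  LogicalMatrix out(nx, ny);
  if (si < 1 || si > nx || sj < 1 || sj > ny) stop("seed outside lattice");
  --si; --sj;
  if (solid(si, sj)) return out;
  std::vector<int> stack;
  stack.push_back(sj * nx + si);
  out(si, sj) = true;
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  while (!stack.empty()) {
    int id = stack.back();
    stack.pop_back();
    int i = id % nx, j = id / nx;
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
      if (out(ii, jj) || solid(ii, jj)) continue;
      out(ii, jj) = true;
      stack.push_back(jj * nx + ii);
    }
  }
  return out;
}
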