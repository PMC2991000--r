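#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// 3D connected-component labelling (iterative flood fill).
// connectivity is 6 or 26; labels are assigned in scan order (deterministic),
// 0 marks background. The label count is returned in attribute "n".
// [[Rcpp::export(name = ".ccLabel3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector lab(n, 0);
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const size_t nn = dxs.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v / nxy);
      int r = (int)(v % nxy);
      int y = r / nx, x = r % nx;
      for (size_t q = 0; q < nn; ++q) {
        int xx = x + dxs[q], yy = y + dys[q], zz = z + dzs[q];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n") = next;
  return lab;
}
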