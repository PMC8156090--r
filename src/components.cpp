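#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling with 26-connectivity (iterative BFS).
// Returns an integer volume of the same shape; 0 = background, components
// numbered from 1 in scan order of their first voxel.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            const R_xlen_t w = xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
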