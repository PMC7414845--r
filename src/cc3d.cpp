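#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connectivity connected-component labelling of a 3D logical mask.
// Returns an integer vector (same length as mask): 0 outside the mask,
// 1..k component ids inside.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = v / ((R_xlen_t)nx * ny);
      int rem = v - (R_xlen_t)z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
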