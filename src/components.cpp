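// 3D connected-component labelling (6/18/26 connectivity) by breadth-first search.
// Components are numbered by the grid-scan-order (linear index) of their first voxel,
// which fixes a deterministic tie-break for equal-size components downstream.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector mask, IntegerVector dims, int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> off1, off2, off3;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        off1.push_back(dx); off2.push_back(dy); off3.push_back(dz);
      }
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int z = (int)(cur / ((R_xlen_t)n1 * n2));
      const int rem = (int)(cur - (R_xlen_t)z * n1 * n2);
      const int y = rem / n1, x = rem % n1;
      for (size_t t = 0; t < off1.size(); ++t) {
        const int xx = x + off1[t], yy = y + off2[t], zz = z + off3[t];
        if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3) continue;
        const R_xlen_t q = (R_xlen_t)zz * n1 * n2 + (R_xlen_t)yy * n1 + xx;
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
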